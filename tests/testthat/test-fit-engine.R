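make_data <- function(p, n = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- generate_true_network(p, nei = if (p >= 5) 2 else 1)
  simulate_studies(net, k = 1, n_range = c(n, n))[[1]]
}

test_that("saturated models recover the closed-form ML solutions", {
  dat <- make_data(5, n = 400, seed = 41)
  fc <- corr_fit(dat)
  expect_true(fc$converged)
  expect_equal(fc$psi, vechs(dat$R), tolerance = 1e-8)
  fg <- ggm_fit(dat)
  expect_true(fg$converged)
  expect_equal(omega_matrix(fg), corr_to_ggm(dat$R), tolerance = 1e-7,
               ignore_attr = TRUE)
  # saturated fit statistics: chi2 = 0, df = 0
  expect_equal(fg$chi2, 0, tolerance = 1e-6)
  expect_equal(fg$df, 0)
})

test_that("bivariate saturated correlation SE equals its closed form", {
  rho <- 0.5; n <- 800
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  fit <- corr_fit(correlation_data(R, n))
  expect_equal(fit$se, sqrt((1 - rho^2)^2 / ((1 + rho^2) * n)),
               tolerance = 1e-10)
})

test_that("parameter covariance agrees with the inverse numeric Hessian", {
  dat <- make_data(4, n = 600, seed = 42)
  fit <- ggm_fit(dat)
  # independent oracle: numeric Hessian of the composed fit function;
  # V = (2/n) solve(H) at the optimum
  f <- function(psi) {
    P <- ggm_to_corr(hollow_from_vechs(psi, 4))
    std_gauss_fit(dat$R, P)
  }
  H <- fd_hessian(f, fit$psi)
  V_num <- (2 / dat$n) * solve(H)
  expect_lt(rel_err(fit$vcov, V_num), 1e-3)
})

test_that("estimates are invariant to variable reordering", {
  dat <- make_data(5, n = 500, seed = 43)
  perm <- c(3, 1, 5, 2, 4)
  dat2 <- correlation_data(dat$R[perm, perm], dat$n)
  f1 <- ggm_fit(dat)
  f2 <- ggm_fit(dat2)
  O1 <- omega_matrix(f1)[perm, perm]
  expect_equal(O1, omega_matrix(f2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a free parameter that never enters the fit raises a singularity error", {
  dat <- make_data(3, n = 300, seed = 44)
  fit <- corr_fit(dat)
  spec <- fit$spec
  # append a dead free-parameter id: no theta row maps to it
  spec$pt$par[1] <- spec$pt$par[1]  # keep
  spec$start <- c(spec$start, 0)
  spec$pt <- rbind(spec$pt, spec$pt[1, ])
  spec$pt$par[nrow(spec$pt)] <- max(spec$pt$par) + 1L
  spec$pt$group[nrow(spec$pt)] <- 1L
  # the extra row is outside every group's row set -> zero Fisher column
  expect_error(fit_ml(spec), "singular|non-identified")
})

test_that("pruning removes weak edges, keeps strong ones, and can empty the model", {
  set.seed(45)
  # strong edges at large n: nothing removed
  net <- generate_true_network(5)
  dat <- simulate_studies(net, k = 1, n_range = c(5000, 5000))[[1]]
  fit <- ggm_fit(dat)
  pruned <- prune(fit, alpha = 0.05)
  true_edges <- vechs(net$omega) != 0
  pt <- pruned$par_table
  kept <- pt$par[pt$mat == "omega"] > 0
  expect_true(all(kept[true_edges]))
  # single true edge of 0.3 at n = 1000 is retained
  Om <- hollow_from_vechs(c(.3, 0, 0), 3)
  P <- ggm_to_corr(Om)
  dat2 <- correlation_data(P, 1000)  # population matrix as data
  f2 <- prune(ggm_fit(dat2), alpha = 0.05)
  expect_true(f2$par_table$par[1] > 0)
  # empty truth can give an empty model
  dat3 <- correlation_data(diag(4), 200)
  f3 <- prune(ggm_fit(dat3), alpha = 0.05)
  expect_equal(f3$npar, 0L)
  expect_true(f3$converged)
})

test_that("per-edge false inclusion under pruning is calibrated near alpha", {
  set.seed(46)
  reps <- 150
  p <- 4
  false_inc <- numeric(0)
  for (r in seq_len(reps)) {
    Y <- matrix(rnorm(250 * p), 250, p)
    dat <- correlation_data(cor(Y), 250)
    fit <- prune(ggm_fit(dat), alpha = 0.05)
    pt <- fit$par_table
    false_inc <- c(false_inc, pt$par[pt$mat == "omega"] > 0)
  }
  expect_gt(mean(false_inc), 0.02)
  expect_lt(mean(false_inc), 0.08)
})

test_that("information criteria prefer the generating sparse model", {
  set.seed(47)
  Om <- hollow_from_vechs(c(.35, 0, 0, .3, 0, .25), 4)
  P <- ggm_to_corr(Om)
  Y <- MASS::mvrnorm(2000, rep(0, 4), P)
  dat <- correlation_data(cor(Y), 2000)
  sat <- ggm_fit(dat)
  sparse <- ggm_fit(dat, pattern = vechs(Om) != 0)
  expect_lt(sparse$BIC, sat$BIC)
  # the true constrained model fits well: RMSEA near zero
  expect_lt(sparse$rmsea, 0.05)
  # LRT between nested models is consistent with the chi2 difference
  out <- lrt(sparse, sat)
  expect_equal(out$statistic, sparse$chi2 - sat$chi2, tolerance = 1e-6)
  expect_equal(out$df, sat$npar - sparse$npar)
  # non-nested (different data) comparisons error
  other <- ggm_fit(make_data(5, n = 300))
  expect_error(lrt(sparse, other), "nested")
})

test_that("modification indices approximate the chi-square gain of freeing", {
  set.seed(48)
  # moderate misfit: one constrained edge whose true value is 0.15
  Om <- hollow_from_vechs(c(.35, .15, 0, .3, 0, .25), 4)
  P <- ggm_to_corr(Om)
  Y <- MASS::mvrnorm(3000, rep(0, 4), P)
  dat <- correlation_data(cor(Y), 3000)
  pat <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
  constrained <- ggm_fit(dat, pattern = pat)
  mi <- modification_indices(constrained)
  # the largest index points at the truly nonzero constrained edge (3,1)
  expect_equal(c(mi$row[1], mi$col[1]), c(3L, 1L))
  freed_pat <- pat; freed_pat[2] <- TRUE
  freed <- ggm_fit(dat, pattern = freed_pat)
  drop_chi2 <- lrt(freed, constrained)$statistic
  expect_lt(abs(mi$mi[1] - drop_chi2) / drop_chi2, 0.2)
  # an all-free model has no candidates
  expect_equal(nrow(modification_indices(ggm_fit(dat))), 0L)
})

test_that("modification indices are chi-square(1) under a true constraint", {
  set.seed(49)
  Om <- hollow_from_vechs(c(.35, 0, .3), 3)
  P <- ggm_to_corr(Om)
  pat <- c(TRUE, FALSE, TRUE)
  mis <- replicate(150, {
    Y <- MASS::mvrnorm(400, rep(0, 3), P)
    fit <- ggm_fit(correlation_data(cor(Y), 400), pattern = pat)
    mi <- modification_indices(fit)
    mi$mi[1]
  })
  expect_equal(mean(mis), 1, tolerance = 0.35)       # E[chi2_1] = 1
  expect_gt(stats::ks.test(mis, "pchisq", df = 1)$p.value, 0.01)
})
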