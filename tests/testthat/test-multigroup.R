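sim_studies <- function(p, k, n_range, seed) {
  set.seed(seed)
  net <- generate_true_network(p, nei = if (p >= 5) 2 else 1)
  list(net = net, studies = simulate_studies(net, k = k, n_range = n_range))
}

test_that("pooling identical matrices returns their correlations", {
  set.seed(51)
  R <- rand_pd_corr(4)
  d1 <- correlation_data(R, 100)
  d2 <- correlation_data(R, 300)
  pc <- pool_correlations(list(d1, d2))
  expect_equal(pc$rho, vechs(R), tolerance = 1e-8)
  # k = 1 reduces to the single-dataset saturated estimate
  pc1 <- pool_correlations(list(d1))
  expect_equal(pc1$rho, vechs(R), tolerance = 1e-8)
})

test_that("pooled bivariate correlation matches a brute-force 1-D minimization", {
  d1 <- correlation_data(matrix(c(1, .4, .4, 1), 2, 2), 100)
  d2 <- correlation_data(matrix(c(1, .6, .6, 1), 2, 2), 300)
  pc <- pool_correlations(list(d1, d2))
  # independent oracle: direct grid/Brent minimization of the weighted fit
  fobj <- function(r) {
    P <- matrix(c(1, r, r, 1), 2, 2)
    (100 / 400) * std_gauss_fit(d1$R, P) + (300 / 400) * std_gauss_fit(d2$R, P)
  }
  brute <- stats::optimize(fobj, c(-0.99, 0.99), tol = 1e-12)$minimum
  expect_lt(abs(as.numeric(pc$rho) - brute), 1e-8)
  # Fisher information matches the numeric Hessian of the weighted fit
  H <- fd_hessian(fobj, pc$rho)
  expect_lt(rel_err(pc$information, H / 2), 1e-5)
})

test_that("combined gradient equals the weighted sum of group gradients", {
  out <- sim_studies(4, 3, c(200, 400), seed = 52)
  pc <- pool_correlations(out$studies)
  n <- sum(sapply(out$studies, function(d) d$n))
  P <- hollow_from_vechs(pc$rho, 4, diag_value = 1)
  g_sum <- Reduce(`+`, lapply(out$studies, function(d)
    (d$n / n) * std_gauss_jacobian(d$R, P)))
  expect_equal(max(abs(g_sum)), 0, tolerance = 1e-7)
})

test_that("two-stage and multi-dataset saturated fits agree in estimates and SEs", {
  out <- sim_studies(5, 3, c(250, 700), seed = 53)
  ts <- two_stage_fixed(out$studies)
  md <- multidataset_ggm(out$studies, "pooled")
  expect_lt(max(abs(ts$psi - md$psi)), 1e-6)
  expect_lt(max(abs(ts$se - md$se)), 1e-6)
})

test_that("splitting a dataset with full equality constraints changes nothing", {
  out <- sim_studies(4, 1, c(1000, 1000), seed = 54)
  d <- out$studies[[1]]
  half <- correlation_data(d$R, d$n / 2)
  md <- multidataset_ggm(list(half, half), "pooled")
  single <- ggm_fit(d)
  expect_lt(max(abs(md$psi - single$psi)), 1e-6)
  expect_lt(max(abs(md$se - single$se)), 1e-6)
})

test_that("unique-per-group specification reproduces separate fits", {
  out <- sim_studies(4, 2, c(300, 500), seed = 55)
  md <- multidataset_ggm(out$studies, "unique")
  for (i in 1:2) {
    sep <- ggm_fit(out$studies[[i]])
    expect_equal(omega_matrix(md, i), omega_matrix(sep), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("partial equality constraints produce the documented psi mapping", {
  out <- sim_studies(3, 2, c(400, 400), seed = 56)
  # first edge unique per dataset, remaining edges pooled
  md <- multidataset_ggm(out$studies, c("unique", "pooled", "pooled"))
  pt <- md$par_table
  g1 <- pt[pt$group == 1, ]
  g2 <- pt[pt$group == 2, ]
  # edge (2,1): distinct parameters; edges (3,1), (3,2): shared
  expect_false(g1$par[1] == g2$par[1])
  expect_equal(g1$par[2:3], g2$par[2:3])
  expect_equal(md$npar, 4L)
})

test_that("stage-2 weight choices leave the saturated point estimate unchanged", {
  out <- sim_studies(4, 2, c(300, 600), seed = 57)
  ts_f <- two_stage_fixed(out$studies, weights = "fisher")
  ts_u <- two_stage_fixed(out$studies, weights = "uls")
  # saturated WLS solution equals the transformed pooled correlations
  expect_equal(ts_f$psi, ts_u$psi, tolerance = 1e-6)
})

test_that("label mismatches across datasets are rejected", {
  R <- rand_pd_corr(3)
  d1 <- correlation_data(R, 100, labels = c("a", "b", "c"))
  d2 <- correlation_data(R, 100, labels = c("a", "b", "d"))
  expect_error(multidataset_ggm(list(d1, d2)), "same variables")
})

test_that("partial pruning frees a genuinely different edge and stays conservative", {
  set.seed(58)
  net <- generate_true_network(6)
  pairs_e <- which(vechs(net$omega) != 0)[1]
  v <- vechs(net$omega)
  v[pairs_e] <- v[pairs_e] - 0.3
  om2 <- hollow_from_vechs(v, 6)
  net2 <- net; net2$omega <- om2; net2$P <- ggm_to_corr(om2)
  s1 <- simulate_studies(net, k = 2, n_range = c(2000, 2000))
  s2 <- simulate_studies(net2, k = 2, n_range = c(2000, 2000))
  pp <- partial_prune(c(s1, s2))
  expect_gte(length(pp$freed), 1L)
  # homogeneous data: the search stays (near) fully pooled
  s3 <- simulate_studies(net, k = 4, n_range = c(500, 500))
  pp2 <- partial_prune(s3)
  expect_lte(length(pp2$freed), 1L)
  expect_error(partial_prune(s3[1]), "at least two")
})
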