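re_setup <- function(p, k, re_sd, n_range = c(300, 800), seed = 1) {
  set.seed(seed)
  net <- generate_true_network(p, nei = if (p >= 5) 2 else 1)
  q <- p * (p - 1) / 2
  re_cov <- generate_re_cov(q, re_sd)
  studies <- simulate_studies(net, k = k, re_cov = re_cov, n_range = n_range)
  list(net = net, studies = studies, q = q)
}

test_that("study rows align to the master vechs order, with NA at missing pairs", {
  set.seed(61)
  R4 <- rand_pd_corr(4)
  labs <- c("a", "b", "c", "d")
  full <- correlation_data(R4, 100, labels = labs)
  sub_idx <- c(1, 2, 4)  # variable "c" missing
  sub <- correlation_data(R4[sub_idx, sub_idx], 80, labels = labs[sub_idx])
  rows <- build_rows(list(full, sub))
  expect_equal(rows$r[1, ], vechs(R4), ignore_attr = TRUE)
  # index bookkeeping oracle: pair (i, j) lives at the position of the
  # strict lower triangle enumerated column by column
  pair_names <- outer(labs, labs, paste, sep = "--")
  expect_equal(colnames(rows$r),
               pair_names[lower.tri(pair_names)])
  miss <- is.na(rows$r[2, ])
  involves_c <- grepl("c", colnames(rows$r))
  expect_equal(miss, involves_c, ignore_attr = TRUE)
  expect_equal(rows$r[2, !miss],
               vechs(R4)[!involves_c], ignore_attr = TRUE)
})

test_that("sampling covariance estimates follow the closed forms", {
  # p = 2: V = (1 - r^2)^2 / ((1 + r^2) n)
  r <- 0.4; n <- 200
  d <- correlation_data(matrix(c(1, r, r, 1), 2, 2), n)
  sc <- estimate_sampling_cov(list(d, d), method = "individual")
  expect_equal(sc$V_i[[1]][1, 1], (1 - r^2)^2 / ((1 + r^2) * n),
               tolerance = 1e-10)
  # pooled scaling: doubling n_i halves V_i exactly
  d2 <- correlation_data(matrix(c(1, r, r, 1), 2, 2), 2 * n)
  scp <- estimate_sampling_cov(list(d, d2), method = "pooled")
  expect_equal(scp$V_i[[2]], scp$V_i[[1]] / 2, tolerance = 1e-12)
  # on identical equal-n studies both constructions estimate the same matrix
  sci <- estimate_sampling_cov(list(d, d), method = "individual")
  scp2 <- estimate_sampling_cov(list(d, d), method = "pooled")
  expect_equal(sci$V_star, scp2$V_star, tolerance = 1e-6)
})

test_that("all four random-effects variants agree on homogeneous equal-n data", {
  out <- re_setup(4, k = 10, re_sd = 0, n_range = c(500, 500), seed = 62)
  rows <- build_rows(out$studies)
  fits <- list()
  for (sampling in c("individual", "pooled")) {
    sc <- estimate_sampling_cov(out$studies, method = sampling)
    for (estimation in c("averaged", "per_study")) {
      fits[[paste(sampling, estimation)]] <-
        fit_random_effects(rows, sc, estimation = estimation)
    }
  }
  q <- out$q
  omegas <- sapply(fits, function(f) f$psi[seq_len(q)])
  for (i in 2:4) expect_gt(cor(omegas[, 1], omegas[, i]), 0.98)
})

test_that("with T fixed at zero the model reduces to a weighted fixed-effects fit", {
  out <- re_setup(4, k = 6, re_sd = 0, seed = 63)
  sc <- estimate_sampling_cov(out$studies, method = "pooled")
  fit0 <- fit_random_effects(build_rows(out$studies), sc,
                             estimation = "per_study", fix_tau = 0)
  ts <- two_stage_fixed(out$studies)
  expect_equal(fit0$psi, ts$psi, tolerance = 1e-4)
})

test_that("heterogeneity SDs are recovered and never pruned", {
  out <- re_setup(4, k = 24, re_sd = 0.1, seed = 64)
  sc <- estimate_sampling_cov(out$studies, method = "individual")
  fit <- fit_random_effects(build_rows(out$studies), sc,
                            estimation = "averaged")
  expect_true(fit$converged)
  # Sigma_ran is PSD by construction and its SDs sit near the truth
  ev <- eigen(fit$Sigma_ran, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_lt(abs(mean(fit$re_sd) - 0.1), 0.06)
  pruned <- prune_random_effects(fit, alpha = 0.05)
  pt <- pruned$par_table
  # every tau parameter survives pruning
  expect_true(all(pt$par[pt$mat == "tau"] > 0))
  # strong edges survive pruning
  strong <- abs(vechs(out$net$omega)) > 0.2
  kept <- pt$par[pt$mat == "omega"] > 0
  expect_true(mean(kept[strong]) > 0.5)
})

test_that("averaged estimation requires complete rows; one study errors", {
  out <- re_setup(4, k = 3, re_sd = 0, seed = 65)
  sub <- out$studies[[1]]
  sub2 <- correlation_data(sub$R[1:3, 1:3], sub$n, labels = sub$labels[1:3])
  studies <- c(out$studies[-1], list(sub2))
  sc <- estimate_sampling_cov(studies, method = "individual")
  rows <- build_rows(studies)
  expect_error(fit_random_effects(rows, sc, estimation = "averaged"),
               "complete rows")
  expect_error(fit_random_effects(build_rows(out$studies[1]),
                                  estimate_sampling_cov(out$studies[1:2])),
               "at least two")
})

test_that("per-study estimation accommodates a study with a missing variable", {
  out <- re_setup(4, k = 8, re_sd = 0, n_range = c(500, 500), seed = 66)
  sub <- out$studies[[8]]
  sub2 <- correlation_data(sub$R[1:3, 1:3], sub$n, labels = sub$labels[1:3])
  studies <- c(out$studies[-8], list(sub2))
  sc <- estimate_sampling_cov(studies, method = "individual")
  fit <- fit_random_effects(build_rows(studies), sc, estimation = "per_study")
  expect_true(fit$converged)
  full <- fit_random_effects(build_rows(out$studies[-8]),
                             estimate_sampling_cov(out$studies[-8],
                                                   "individual"),
                             estimation = "per_study")
  q <- out$q
  expect_gt(cor(fit$psi[seq_len(q)], full$psi[seq_len(q)]), 0.95)
})
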