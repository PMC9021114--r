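test_that("standardized Gaussian fit matches hand-computed values", {
  I2 <- diag(2)
  expect_equal(std_gauss_fit(I2, I2), 2)
  P5 <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_equal(std_gauss_fit(P5, P5), 2 - log(4 / 3), tolerance = 1e-12)
  expect_equal(std_gauss_fit(P5, I2), 2)
  expect_error(std_gauss_fit(I2, matrix(c(1, 1, 1, 1), 2, 2)), "P")
})

test_that("standardized Gaussian Jacobian is zero at R = P and matches hand value", {
  P5 <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_equal(as.numeric(std_gauss_jacobian(P5, P5)), 0)
  # p = 2, R off-diag .5, P = I: -vec(I (R - I) I)' Dstar = -1
  expect_equal(as.numeric(std_gauss_jacobian(P5, diag(2))), -1)
})

test_that("standardized Gaussian derivatives match finite differences", {
  set.seed(21)
  p <- 4
  R <- rand_pd_corr(p)
  P <- rand_pd_corr(p)
  f <- function(rho) std_gauss_fit(R, hollow_from_vechs(rho, p, diag_value = 1))
  expect_lt(rel_err(std_gauss_jacobian(R, P), fd_jacobian(f, vechs(P))), 1e-6)
  fsat <- function(rho) std_gauss_fit(P, hollow_from_vechs(rho, p, diag_value = 1))
  expect_lt(rel_err(std_gauss_hessian(P), fd_hessian(fsat, vechs(P))), 1e-5)
})

test_that("distribution Hessian has the bivariate closed form", {
  expect_equal(as.numeric(std_gauss_hessian(diag(2))), 2)
  for (rho in c(-0.6, 0.2, 0.8)) {
    P <- matrix(c(1, rho, rho, 1), 2, 2)
    expect_equal(as.numeric(std_gauss_hessian(P)),
                 2 * (1 + rho^2) / (1 - rho^2)^2, tolerance = 1e-12)
  }
})

test_that("fit is minimized at the saturated solution P = R", {
  set.seed(22)
  for (i in 1:5) {
    R <- rand_pd_corr(4)
    P <- rand_pd_corr(4)
    expect_gte(std_gauss_fit(R, P), std_gauss_fit(R, R) - 1e-12)
  }
})

test_that("weighted least squares fit, Jacobian and Hessian behave", {
  z <- c(1, 2, 3)
  W <- diag(3)
  expect_equal(wls_fit(z, z, W), 0)
  expect_equal(as.numeric(wls_jacobian(z, z, W)), c(0, 0, 0))
  expect_equal(wls_fit(c(1, 2), c(0, 0), diag(2)), 5)
  expect_error(wls_fit(z, c(1, 2), W), "length")
  set.seed(23)
  W <- crossprod(matrix(rnorm(9), 3, 3))
  phi <- rnorm(3)
  f <- function(x) wls_fit(z, x, W)
  expect_lt(rel_err(wls_jacobian(z, phi, W), fd_jacobian(f, phi)), 1e-6)
  expect_lt(rel_err(wls_hessian(W), fd_hessian(f, phi)), 1e-6)
})

test_that("study-level Gaussian fit equals -2/k times the summed log-density", {
  set.seed(24)
  k <- 7; q <- 3
  rmat <- matrix(rnorm(k * q, sd = .3), k, q)
  rbar <- colMeans(rmat)
  S <- crossprod(sweep(rmat, 2, rbar)) / k
  mu <- rnorm(q, sd = .2)
  Sigma <- rand_pd_corr(q) * 0.5 + diag(q) * 0.5
  # independent oracle: direct Gaussian log-density summation
  K <- solve(Sigma)
  ll <- sum(apply(rmat, 1, function(r) {
    -0.5 * (q * log(2 * pi) + determinant(Sigma)$modulus +
              drop(t(r - mu) %*% K %*% (r - mu)))
  }))
  expect_equal(meta_gauss_fit(rbar, S, mu, Sigma),
               -2 / k * ll - q * log(2 * pi), tolerance = 1e-10)
  # trivial values
  expect_equal(meta_gauss_fit(mu, matrix(0, q, q), mu, diag(q)), 0)
  expect_equal(meta_gauss_fit(mu[1:2], diag(2), mu[1:2], diag(2)), 2)
})

test_that("study-level Gaussian derivatives match finite differences", {
  set.seed(25)
  q <- 3
  rbar <- rnorm(q, sd = .2)
  S <- crossprod(matrix(rnorm(4 * q), 4, q)) / 4
  mu <- rnorm(q, sd = .2)
  Sigma <- rand_pd_corr(q) * 0.5 + diag(q) * 0.5
  f <- function(par) meta_gauss_fit(rbar, S, par[1:q],
                                    sym_from_vech(par[-(1:q)], q))
  par0 <- c(mu, vech(Sigma))
  expect_lt(rel_err(meta_gauss_jacobian(rbar, S, mu, Sigma),
                    fd_jacobian(f, par0)), 1e-6)
  # mean-block Jacobian vanishes when mu = rbar
  jz <- meta_gauss_jacobian(rbar, S, rbar, Sigma)
  expect_equal(as.numeric(jz[1, 1:q]), rep(0, q))
  # Hessian mean block is 2K; at Sigma = I that is 2I
  H <- meta_gauss_hessian(diag(q))
  expect_equal(H[1:q, 1:q], 2 * diag(q))
})

test_that("correlation data validates its invariants", {
  R <- rand_pd_corr(3)
  expect_s3_class(correlation_data(R, 10), "correlation_data")
  expect_error(correlation_data(R, 3), "n must be at least")
  expect_error(correlation_data(R[, 1:2, drop = FALSE], 10), "square")
  R2 <- R; R2[1, 2] <- R2[1, 2] + 1e-3
  expect_error(correlation_data(R2, 10), "symmetric")
  # indefinite matrices warn but construct
  Rbad <- matrix(0.99, 3, 3); Rbad[1, 2] <- Rbad[2, 1] <- -0.99; diag(Rbad) <- 1
  expect_warning(correlation_data(Rbad, 10), "positive definite")
})
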