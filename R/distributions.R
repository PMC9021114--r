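#' Study-level correlation data
#'
#' Container for one study's sample correlation matrix together with its
#' sample size and variable labels. The matrix is validated for symmetry
#' and a unit diagonal; a warning (not an error) is issued when the
#' smallest eigenvalue is non-positive, since pairwise-complete empirical
#' correlation matrices can be slightly indefinite and estimation may
#' still proceed.
#'
#' @param R A p x p sample correlation matrix.
#' @param n Sample size (number of cases), at least p + 1.
#' @param labels Optional character vector of p variable names.
#' @return An object of class `correlation_data`: a list with elements
#'   `R`, `n`, `labels`, `p` and `min_eigen`.
#' @export
correlation_data <- function(R, n, labels = NULL) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (ncol(R) != p) stop("correlation matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("correlation matrix must have a unit diagonal")
  n <- as.integer(n)
  if (is.na(n) || n < p + 1L)
    stop("sample size n must be at least p + 1")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(R))) rownames(R) else paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("labels must have length p")
  dimnames(R) <- list(labels, labels)
  min_eigen <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eigen <= 0)
    warning(sprintf(
      "sample correlation matrix is not positive definite (min eigenvalue %.3g)",
      min_eigen))
  structure(list(R = R, n = n, labels = labels, p = p, min_eigen = min_eigen),
            class = "correlation_data")
}

#' @export
print.correlation_data <- function(x, ...) {
  cat(sprintf("Correlation data: %d variables, n = %d\n", x$p, x$n))
  print(round(x$R, 3))
  invisible(x)
}

# Symmetric inverse through a Cholesky factorization; `what` names the
# matrix in the error raised when the factorization fails.
sym_inverse <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("%s is singular or not positive definite", what))
  chol2inv(ch)
}

log_det_pd <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("%s is singular or not positive definite", what))
  2 * sum(log(diag(ch)))
}

#' Standardized Gaussian fit function on correlation matrices
#'
#' The -2/n log-likelihood (up to an additive constant) of standardized
#' multivariate Gaussian data with sample correlation matrix `R` under a
#' model correlation matrix `P`: `F = trace(R K) - log det K`, where
#' `K = solve(P)`. Minimized over unconstrained unit-diagonal `P` at
#' `P = R`.
#'
#' @param R Sample correlation matrix.
#' @param P Model (implied) correlation matrix, positive definite.
#' @return A scalar fit value.
#' @export
std_gauss_fit <- function(R, P) {
  K <- sym_inverse(P, "model correlation matrix P")
  # -ln|K| = +ln|P|
  sum(R * K) + log_det_pd(P, "model correlation matrix P")
}

#' Derivatives of the standardized Gaussian fit function
#'
#' `std_gauss_jacobian()` returns the row vector of first derivatives of
#' the fit with respect to the strict half-vectorized correlations
#' `rho = vechs(P)`: `-vec(K (R - P) K)' Dstar`. `std_gauss_hessian()`
#' returns the expected second derivative (distribution Hessian)
#' `t(Dstar) (K %x% K) Dstar`, which is positive definite for positive
#' definite `P`.
#'
#' @inheritParams std_gauss_fit
#' @return A 1 x q matrix (Jacobian) or a q x q matrix (Hessian),
#'   q = p(p-1)/2.
#' @export
std_gauss_jacobian <- function(R, P) {
  K <- sym_inverse(P, "model correlation matrix P")
  sm <- structural_matrices(nrow(P))
  res <- -Matrix::crossprod(vec(K %*% (R - P) %*% K), sm$Dstar)
  as.matrix(res)
}

#' @rdname std_gauss_jacobian
#' @export
std_gauss_hessian <- function(P) {
  K <- sym_inverse(P, "model correlation matrix P")
  sm <- structural_matrices(nrow(P))
  as.matrix(Matrix::t(sm$Dstar) %*% (K %x% K) %*% sm$Dstar)
}

#' Weighted least squares fit function and derivatives
#'
#' `F = (z - phi)' W (z - phi)` with symmetric positive semi-definite
#' weight matrix `W`; with `W = I` this is unweighted least squares and
#' with diagonal `W` diagonally weighted least squares. Used as the
#' stage-2 estimator in two-stage fixed-effects aggregation, where `z`
#' holds pooled correlation estimates and `W` their Fisher information.
#'
#' @param z Observed statistic vector.
#' @param phi Model-implied vector, same length as `z`.
#' @param W Weight matrix.
#' @return A scalar (fit), a 1 x length(z) matrix (Jacobian), or the
#'   matrix `2 W` (Hessian).
#' @export
wls_fit <- function(z, phi, W) {
  d <- check_wls_dims(z, phi, W)
  drop(crossprod(d, W %*% d))
}

#' @rdname wls_fit
#' @export
wls_jacobian <- function(z, phi, W) {
  d <- check_wls_dims(z, phi, W)
  -2 * t(W %*% d)
}

#' @rdname wls_fit
#' @export
wls_hessian <- function(W) {
  2 * as.matrix(W)
}

check_wls_dims <- function(z, phi, W) {
  z <- as.numeric(z); phi <- as.numeric(phi)
  if (length(z) != length(phi))
    stop("z and phi must have the same length")
  if (nrow(W) != length(z) || ncol(W) != length(z))
    stop("weight matrix W has wrong dimensions")
  z - phi
}

#' Gaussian fit function for study-level correlation vectors
#'
#' The fit function used in random-effects aggregation, where each study
#' contributes a vector of sample correlations modeled as multivariate
#' Gaussian with mean `mu` and covariance `Sigma`:
#' `F = trace(S K) + (rbar - mu)' K (rbar - mu) - log det K`,
#' `K = solve(Sigma)`. With `S = 0` and `rbar = r_i` this is the
#' per-study (FIML) fit function; with `rbar` the across-study mean and
#' `S` the across-study scatter it is the averaged-estimation fit, equal
#' to -2/k times the Gaussian log-likelihood of the k study rows up to an
#' additive constant.
#'
#' @param rbar Mean (or single-study) correlation vector.
#' @param S Scatter matrix of study correlation vectors (zero matrix for
#'   the per-study form).
#' @param mu Model-implied mean vector.
#' @param Sigma Model covariance matrix, positive definite.
#' @return Scalar fit value.
#' @export
meta_gauss_fit <- function(rbar, S, mu, Sigma) {
  K <- sym_inverse(Sigma, "model covariance matrix Sigma")
  d <- as.numeric(rbar) - as.numeric(mu)
  sum(S * K) + drop(crossprod(d, K %*% d)) + log_det_pd(Sigma, "Sigma")
}

#' Derivatives of the study-level Gaussian fit function
#'
#' Jacobian blocks with respect to `mu` and `sigma = vech(Sigma)`:
#' `dF/dmu = -2 (rbar - mu)' K` and
#' `dF/dsigma = -vec(K (S + d d' - Sigma) K)' D` with `d = rbar - mu` and
#' `D` the duplication matrix. The expected Hessian is block diagonal with
#' blocks `2 K` (mean part) and `t(D) (K %x% K) D` (covariance part).
#'
#' @inheritParams meta_gauss_fit
#' @return `meta_gauss_jacobian()`: a 1 x (q + q(q+1)/2) matrix;
#'   `meta_gauss_hessian()`: the corresponding block-diagonal matrix.
#' @export
meta_gauss_jacobian <- function(rbar, S, mu, Sigma) {
  Sigma <- as.matrix(Sigma)
  K <- sym_inverse(Sigma, "model covariance matrix Sigma")
  d <- as.numeric(rbar) - as.numeric(mu)
  j_mu <- -2 * crossprod(d, K)
  M <- S + tcrossprod(d) - Sigma
  KMK <- K %*% M %*% K
  if (nrow(Sigma) == 1L) {
    j_sigma <- -KMK
  } else {
    sm <- structural_matrices(nrow(Sigma))
    j_sigma <- -Matrix::crossprod(vec(KMK), sm$D)
  }
  cbind(as.matrix(j_mu), as.matrix(j_sigma))
}

#' @rdname meta_gauss_jacobian
#' @export
meta_gauss_hessian <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  K <- sym_inverse(Sigma, "model covariance matrix Sigma")
  q <- nrow(Sigma)
  H_mu <- 2 * K
  if (q == 1L) {
    H_sigma <- K %x% K
  } else {
    sm <- structural_matrices(q)
    H_sigma <- as.matrix(Matrix::t(sm$D) %*% (K %x% K) %*% sm$D)
  }
  out <- matrix(0, q + nrow(H_sigma), q + nrow(H_sigma))
  out[seq_len(q), seq_len(q)] <- H_mu
  out[-seq_len(q), -seq_len(q)] <- H_sigma
  out
}
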