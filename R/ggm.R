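#' Convert between partial-correlation networks and correlation matrices
#'
#' A Gaussian graphical model is parameterized by a hollow symmetric
#' matrix `Omega` of partial correlations. The implied correlation matrix
#' is `P = Delta solve(I - Omega) Delta`, where the diagonal scaling
#' `Delta = vec2diag(diag(solve(I - Omega)))^(-1/2)` ensures a unit
#' diagonal. `corr_to_ggm()` inverts the map through the precision
#' matrix: `omega_ij = -kappa_ij / sqrt(kappa_ii kappa_jj)` with
#' `kappa = solve(P)`, so edges are partial correlations.
#'
#' @param Omega Hollow symmetric matrix of partial correlations.
#' @param P Positive definite correlation matrix (unit diagonal).
#' @return `ggm_to_corr()`: the implied correlation matrix;
#'   `corr_to_ggm()`: the partial-correlation matrix. The two maps are
#'   mutual inverses.
#' @export
ggm_to_corr <- function(Omega) {
  Omega <- as.matrix(Omega)
  p <- nrow(Omega)
  IminO <- diag(p) - Omega
  Ostar <- tryCatch(solve(IminO), error = function(e) NULL)
  if (is.null(Ostar))
    stop("I - Omega is singular; the network is outside the admissible region")
  d <- diag(Ostar)
  if (any(d <= 0))
    stop("solve(I - Omega) has non-positive diagonal entries; ",
         "the network is outside the admissible region")
  Delta <- diag(1 / sqrt(d), p)
  P <- Delta %*% Ostar %*% Delta
  (P + t(P)) / 2
}

#' @rdname ggm_to_corr
#' @export
corr_to_ggm <- function(P) {
  P <- as.matrix(P)
  K <- sym_inverse(P, "correlation matrix P")
  d <- sqrt(diag(K))
  Omega <- -K / tcrossprod(d)
  diag(Omega) <- 0
  (Omega + t(Omega)) / 2
}

# Implied correlation matrix, or NULL when the proposal is inadmissible
# (singular I - Omega, non-positive scaling, or indefinite P). Optimizer
# proposals hitting this region are rejected with a +Inf fit value so line
# searches can back off rather than abort.
ggm_implied <- function(Omega) {
  p <- nrow(Omega)
  Ostar <- tryCatch(solve(diag(p) - Omega), error = function(e) NULL)
  if (is.null(Ostar)) return(NULL)
  d <- diag(Ostar)
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  Delta <- diag(1 / sqrt(d), p)
  P <- Delta %*% Ostar %*% Delta
  P <- (P + t(P)) / 2
  if (is.null(tryCatch(chol(P), error = function(e) NULL))) return(NULL)
  P
}

#' Model Jacobian of the GGM map
#'
#' Analytic derivative of the implied correlations `rho = vechs(P)` with
#' respect to the partial correlations `omega = vechs(Omega)`:
#'
#' `Lstar [ (D Os %x% D Os) - 0.5 ((D Os %x% I) + (I %x% D Os)) A
#'   dmat(Os)^(-3/2) t(A) (Os %x% Os) ] Dstar`
#'
#' with `Os = solve(I - Omega)` and `D` the diagonal scaling of the GGM
#' map; the power -3/2 acts on the diagonal entries only. In the
#' bivariate case the map is the identity.
#'
#' @param Omega Hollow symmetric matrix of partial correlations.
#' @return A q x q matrix, q = p(p-1)/2.
#' @export
ggm_model_jacobian <- function(Omega) {
  Omega <- as.matrix(Omega)
  p <- nrow(Omega)
  Ostar <- tryCatch(solve(diag(p) - Omega), error = function(e) NULL)
  if (is.null(Ostar))
    stop("I - Omega is singular; the network is outside the admissible region")
  dOs <- diag(Ostar)
  if (any(dOs <= 0))
    stop("solve(I - Omega) has non-positive diagonal entries")
  Delta <- diag(1 / sqrt(dOs), p)
  DO <- Delta %*% Ostar
  sm <- structural_matrices(p)
  inner <- (DO %x% DO) -
    0.5 * ((DO %x% diag(p)) + (diag(p) %x% DO)) %*%
      (as.matrix(sm$A) %*% diag(dOs^(-3 / 2), p) %*% Matrix::t(sm$A)) %*%
      (Ostar %x% Ostar)
  as.matrix(sm$Lstar %*% inner %*% sm$Dstar)
}

#' Model Jacobian of the Cholesky covariance parameterization
#'
#' For a covariance component `Sigma_ran = T t(T)` with lower-triangular
#' `T` and parameters `tau = vech(T)`, the derivative of
#' `sigma = vech(T t(T))` with respect to `tau` is
#' `L ((I %x% I) + C) (T %x% I) t(L)`, with `L` the elimination and `C`
#' the commutation matrix of the relevant dimension.
#'
#' @param T_mat Lower-triangular matrix.
#' @return A q(q+1)/2 x q(q+1)/2 matrix, q = nrow(T_mat).
#' @export
cholesky_model_jacobian <- function(T_mat) {
  T_mat <- as.matrix(T_mat)
  q <- nrow(T_mat)
  if (any(T_mat[upper.tri(T_mat)] != 0))
    stop("T must be lower triangular")
  if (q == 1L) return(matrix(2 * T_mat[1, 1], 1, 1))
  sm <- structural_matrices(q)
  IplusC <- Matrix::Diagonal(q * q) + sm$C
  as.matrix(sm$L %*% IplusC %*% ((T_mat %x% diag(q)) %*% Matrix::t(sm$L)))
}
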