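# Shared fixtures and independent numeric oracles.

# Random positive definite correlation matrix.
rand_pd_corr <- function(p, df = p + 5) {
  W <- crossprod(matrix(rnorm(df * p), df, p))
  stats::cov2cor(W)
}

# Random admissible hollow partial-correlation matrix (via the inverse
# transform of a random correlation matrix, guaranteed admissible).
rand_omega <- function(p, scale = 1) {
  corr_to_ggm(rand_pd_corr(p)) * scale
}

# Central finite differences, independent of the package's analytic
# derivatives.
fd_jacobian <- function(f, x) pracma::jacobian(f, x)
fd_hessian <- function(f, x) pracma::hessian(f, x)

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)

# Rebuild helpers mirroring the column-stacked lower-triangle convention
# (kept independent of package internals for ordering checks).
hollow_from_vechs <- function(x, p, diag_value = 0) {
  M <- matrix(0, p, p)
  M[lower.tri(M)] <- x
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

sym_from_vech <- function(x, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- x
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

lower_from_vech <- function(x, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- x
  M
}
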