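#' Vectorization operators
#'
#' Column-stacked (half-)vectorization of matrices and their inverses.
#' `vec()` stacks all columns, `vech()` stacks the lower triangle including
#' the diagonal, and `vechs()` stacks the strict lower triangle (diagonal
#' omitted). All orderings enumerate the lower triangle column by column;
#' every parameter vector in this package inherits this ordering.
#'
#' @param M A square numeric matrix.
#' @return A numeric vector.
#' @examples
#' M <- matrix(c(1, .3, .2, .3, 1, .5, .2, .5, 1), 3, 3)
#' vechs(M) # .3 .2 .5
#' @export
vec <- function(M) {
  as.vector(as.matrix(M))
}

#' @rdname vec
#' @export
vech <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("vech() requires a square matrix")
  M[lower.tri(M, diag = TRUE)]
}

#' @rdname vec
#' @export
vechs <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("vechs() requires a square matrix")
  M[lower.tri(M, diag = FALSE)]
}

#' Diagonal-matrix helpers
#'
#' `vec2diag(v)` returns the diagonal matrix with `v` on its diagonal;
#' `dmat(M)` zeroes every off-diagonal entry of a square matrix.
#'
#' @param v A numeric vector.
#' @param M A square numeric matrix.
#' @return A square matrix.
#' @export
vec2diag <- function(v) {
  diag(as.vector(v), nrow = length(v))
}

#' @rdname vec2diag
#' @export
dmat <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("dmat() requires a square matrix")
  diag(diag(M), nrow = nrow(M))
}

# vec position of element (i, j) in a p x p matrix (column-major)
vec_index <- function(i, j, p) {
  (j - 1L) * p + i
}

# lower-triangle (including diagonal) positions in column-major order
vech_pairs <- function(p) {
  j <- rep(seq_len(p), times = p:1)
  i <- unlist(lapply(seq_len(p), function(col) col:p))
  cbind(i = i, j = j)
}

# strict lower-triangle positions in column-major order
vechs_pairs <- function(p) {
  if (p < 2) return(cbind(i = integer(0), j = integer(0)))
  j <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  i <- unlist(lapply(seq_len(p - 1L), function(col) (col + 1L):p))
  cbind(i = i, j = j)
}

#' Structural matrices for matrix-calculus derivatives
#'
#' Builds the sparse 0/1 matrices that convert between `vec`, `vech` and
#' `vechs` forms of symmetric matrices and that appear throughout the
#' analytic derivatives: the duplication matrix `D` (p^2 x p(p+1)/2), the
#' strict duplication matrix `Dstar` (p^2 x p(p-1)/2), the elimination
#' matrix `L` (p(p+1)/2 x p^2), the strict elimination matrix `Lstar`
#' (p(p-1)/2 x p^2), the commutation matrix `C` (p^2 x p^2), and the
#' diagonal-selection matrix `A` (p^2 x p).
#'
#' They satisfy, for any symmetric `M`: `D %*% vech(M) == vec(M)`; for any
#' hollow symmetric `M`: `Dstar %*% vechs(M) == vec(M)`; for any `M`:
#' `L %*% vec(M) == vech(M)`, `Lstar %*% vec(M) == vechs(M)`,
#' `C %*% vec(M) == vec(t(M))`, and `t(A) %*% vec(M) == diag(M)`.
#'
#' @param p Integer dimension, at least 2.
#' @return A list of class `structural_matrices` with elements `p`, `D`,
#'   `Dstar`, `L`, `Lstar`, `C`, `A` (sparse `Matrix` objects).
#' @export
structural_matrices <- function(p) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 2L)
    stop("structural_matrices() requires an integer dimension p >= 2")
  cached <- .structmat_cache[[as.character(p)]]
  if (!is.null(cached)) return(cached)

  p2 <- p * p
  qh <- p * (p + 1L) / 2L
  qs <- p * (p - 1L) / 2L

  # D: vec(M) = D vech(M) for symmetric M
  ph <- vech_pairs(p)
  rows_lo <- vec_index(ph[, "i"], ph[, "j"], p)
  rows_up <- vec_index(ph[, "j"], ph[, "i"], p)
  off <- ph[, "i"] != ph[, "j"]
  D <- Matrix::sparseMatrix(
    i = c(rows_lo, rows_up[off]),
    j = c(seq_len(qh), seq_len(qh)[off]),
    x = 1, dims = c(p2, qh)
  )

  # Dstar: vec(M) = Dstar vechs(M) for hollow symmetric M
  ps <- vechs_pairs(p)
  srows_lo <- vec_index(ps[, "i"], ps[, "j"], p)
  srows_up <- vec_index(ps[, "j"], ps[, "i"], p)
  Dstar <- Matrix::sparseMatrix(
    i = c(srows_lo, srows_up),
    j = c(seq_len(qs), seq_len(qs)),
    x = 1, dims = c(p2, qs)
  )

  # L: vech(M) = L vec(M); Lstar: vechs(M) = Lstar vec(M)
  L <- Matrix::sparseMatrix(i = seq_len(qh), j = rows_lo, x = 1,
                            dims = c(qh, p2))
  Lstar <- Matrix::sparseMatrix(i = seq_len(qs), j = srows_lo, x = 1,
                                dims = c(qs, p2))

  # C: vec(t(M)) = C vec(M); permutation sending (i,j) -> (j,i)
  ij <- expand.grid(i = seq_len(p), j = seq_len(p))
  C <- Matrix::sparseMatrix(
    i = vec_index(ij$j, ij$i, p),
    j = vec_index(ij$i, ij$j, p),
    x = 1, dims = c(p2, p2)
  )

  # A: t(A) vec(M) = diag(M); A v = vec(diag(v))
  A <- Matrix::sparseMatrix(
    i = vec_index(seq_len(p), seq_len(p), p),
    j = seq_len(p), x = 1, dims = c(p2, p)
  )

  out <- structure(
    list(p = p, D = D, Dstar = Dstar, L = L, Lstar = Lstar, C = C, A = A),
    class = "structural_matrices"
  )
  assign(as.character(p), out, envir = .structmat_cache)
  out
}

.structmat_cache <- new.env(parent = emptyenv())

# Rebuild a hollow symmetric matrix from its strict half-vectorization.
vechs_to_matrix <- function(x, p, diag_value = 0) {
  M <- matrix(0, p, p)
  M[lower.tri(M)] <- x
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

# Rebuild a symmetric matrix from its half-vectorization.
vech_to_matrix <- function(x, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- x
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

# Rebuild a lower-triangular matrix from its half-vectorization.
vech_to_lower <- function(x, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- x
  M
}
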