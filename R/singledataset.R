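# Spec builders for single-dataset models and the user-facing
# single-dataset estimation functions.

# Distribution callbacks for the standardized Gaussian on a sample
# correlation matrix R; phi = vechs(P).
gauss_corr_dist <- function(R) {
  p <- nrow(R)
  list(
    fit = function(phi) {
      P <- vechs_to_matrix(phi, p, diag_value = 1)
      std_gauss_fit(R, P)
    },
    jac = function(phi) {
      P <- vechs_to_matrix(phi, p, diag_value = 1)
      std_gauss_jacobian(R, P)
    },
    hess = function(phi) {
      P <- vechs_to_matrix(phi, p, diag_value = 1)
      std_gauss_hessian(P)
    },
    nphi = p * (p - 1) / 2
  )
}

# Group whose model parameters are GGM edge weights omega.
ggm_group <- function(data, rows, weight) {
  p <- data$p
  dist <- gauss_corr_dist(data$R)
  list(
    rows = rows,
    model = function(th, shared) {
      P <- ggm_implied(vechs_to_matrix(th, p))
      if (is.null(P)) NULL else vechs(P)
    },
    model_jac = function(th, shared) ggm_model_jacobian(vechs_to_matrix(th, p)),
    dist_fit = dist$fit, dist_jac = dist$jac, dist_hess = dist$hess,
    weight = weight, nphi = dist$nphi
  )
}

# Group whose model parameters are the correlations themselves
# (model Jacobian = identity).
corr_group <- function(data, rows, weight) {
  p <- data$p
  dist <- gauss_corr_dist(data$R)
  q <- p * (p - 1) / 2
  list(
    rows = rows,
    model = function(th, shared) {
      P <- vechs_to_matrix(th, p, diag_value = 1)
      if (is.null(tryCatch(chol(P), error = function(e) NULL))) return(NULL)
      th
    },
    model_jac = function(th, shared) diag(q),
    dist_fit = dist$fit, dist_jac = dist$jac, dist_hess = dist$hess,
    weight = weight, nphi = q
  )
}

# Saturated-model fit value of one dataset: F at P = R.
saturated_F <- function(data) {
  data$p + log_det_pd(data$R, "sample correlation matrix R")
}

# Normalize an edge-inclusion pattern to a logical vector over vechs order.
normalize_pattern <- function(pattern, p) {
  q <- p * (p - 1) / 2
  if (is.null(pattern)) return(rep(TRUE, q))
  if (is.matrix(pattern)) {
    if (nrow(pattern) != p || ncol(pattern) != p)
      stop("pattern matrix must be p x p")
    return(as.logical(vechs(pattern != 0)))
  }
  pattern <- as.logical(pattern)
  if (length(pattern) != q) stop("pattern must have length p(p-1)/2")
  pattern
}

# Shrink a candidate Omega toward zero until it is admissible.
admissible_start <- function(omega, p) {
  for (i in 0:40) {
    cand <- omega * 0.9^i
    if (!is.null(ggm_implied(vechs_to_matrix(cand, p)))) return(cand)
  }
  rep(0, length(omega))
}

#' Estimate a Gaussian graphical model from one correlation matrix
#'
#' Maximum likelihood estimation of a (possibly constrained) partial
#' correlation network from a single sample correlation matrix, with
#' standard errors from the Fisher information. For the saturated model
#' the estimate equals the direct transform `corr_to_ggm(R)`; constrained
#' models fix the excluded edges to zero. Use [prune()] on the result for
#' Wald-based significance pruning.
#'
#' @param data A [correlation_data()] object (or a list with `R` and `n`).
#' @param pattern Optional edge-inclusion pattern: logical vector over
#'   `vechs` order or a p x p indicator matrix. `NULL` fits the saturated
#'   model.
#' @param control Passed to [fit_ml()].
#' @return A `ggm_fit` with the edge estimates in `omega_matrix(fit)`.
#' @examples
#' set.seed(1)
#' net <- generate_true_network(8)
#' dat <- simulate_studies(net, k = 1, n_range = c(500, 500))[[1]]
#' fit <- ggm_fit(dat)
#' @export
ggm_fit <- function(data, pattern = NULL, control = list()) {
  data <- as_correlation_data(data)
  p <- data$p
  pat <- normalize_pattern(pattern, p)
  pairs <- vechs_pairs(p)
  q <- nrow(pairs)
  par <- integer(q)
  par[pat] <- seq_len(sum(pat))
  pt <- new_par_table(group = 1L, mat = "omega",
                      row = pairs[, "i"], col = pairs[, "j"],
                      par = par, fixed = 0,
                      label = paste0(data$labels[pairs[, "i"]], "--",
                                     data$labels[pairs[, "j"]]))
  omega0 <- vechs(corr_to_ggm(data$R))
  omega0[!pat] <- 0
  omega0 <- admissible_start(omega0, p)
  spec <- list(pt = pt, groups = list(ggm_group(data, seq_len(q), 1)),
               n = data$n, k = 1L, sat_F = saturated_F(data),
               likelihood = TRUE, ll_const = p * log(2 * pi),
               start = omega0[pat], label = "Gaussian graphical model",
               datasets = list(data), model = "ggm")
  fit_ml(spec, control = control)
}

#' Estimate a (possibly constrained) correlation model
#'
#' Fits the standardized Gaussian distribution directly on the
#' correlations. For the saturated model the ML estimate equals the
#' sample correlation matrix itself; the value of the function lies in
#' the Fisher information and standard errors it provides, and in
#' constrained variants (fixed or equality-constrained correlations)
#' through `pattern`.
#'
#' @inheritParams ggm_fit
#' @return A `ggm_fit`; `corr_matrix(fit)` returns the estimated matrix.
#' @export
corr_fit <- function(data, pattern = NULL, control = list()) {
  data <- as_correlation_data(data)
  p <- data$p
  pat <- normalize_pattern(pattern, p)
  pairs <- vechs_pairs(p)
  q <- nrow(pairs)
  par <- integer(q)
  par[pat] <- seq_len(sum(pat))
  pt <- new_par_table(group = 1L, mat = "rho",
                      row = pairs[, "i"], col = pairs[, "j"],
                      par = par, fixed = 0,
                      label = paste0(data$labels[pairs[, "i"]], "--",
                                     data$labels[pairs[, "j"]]))
  rho0 <- vechs(data$R)
  rho0[!pat] <- 0
  spec <- list(pt = pt, groups = list(corr_group(data, seq_len(q), 1)),
               n = data$n, k = 1L, sat_F = saturated_F(data),
               likelihood = TRUE, ll_const = p * log(2 * pi),
               start = rho0[pat], label = "Correlation model",
               datasets = list(data), model = "corr")
  fit_ml(spec, control = control)
}

as_correlation_data <- function(x) {
  if (inherits(x, "correlation_data")) return(x)
  if (is.list(x) && !is.null(x$R) && !is.null(x$n))
    return(correlation_data(x$R, x$n, x$labels))
  stop("expected a correlation_data object")
}

#' Extract estimated matrices from a fit
#'
#' `omega_matrix()` rebuilds the estimated partial-correlation matrix of
#' a group, `corr_matrix()` the estimated (or implied) correlation
#' matrix.
#'
#' @param fit A `ggm_fit`.
#' @param group Group (dataset) index.
#' @return A p x p matrix.
#' @export
omega_matrix <- function(fit, group = 1L) {
  pt <- fit$par_table
  sel <- pt$group == group & pt$mat == "omega"
  if (!any(sel)) stop("fit has no GGM parameters for group ", group)
  block <- pt[sel, ]
  p <- max(block$row)
  vechs_to_matrix(block$est, p)
}

#' @rdname omega_matrix
#' @export
corr_matrix <- function(fit, group = 1L) {
  pt <- fit$par_table
  sel <- pt$group == group & pt$mat == "rho"
  if (any(sel)) {
    block <- pt[sel, ]
    return(vechs_to_matrix(block$est, max(block$row), diag_value = 1))
  }
  ggm_to_corr(omega_matrix(fit, group))
}

#' Edge table of a fitted network
#'
#' One row per potential edge of the requested group with estimate,
#' standard error, Wald z, p value and inclusion status.
#'
#' @param fit A `ggm_fit`.
#' @param group Group index (`NULL` = all groups).
#' @return A data frame.
#' @export
edge_table <- function(fit, group = NULL) {
  pt <- fit$par_table
  sel <- pt$mat %in% c("omega", "rho")
  if (!is.null(group)) sel <- sel & pt$group %in% group
  out <- pt[sel, c("group", "row", "col", "label", "est", "se", "z", "p", "par")]
  names(out)[names(out) == "est"] <- "weight"
  out$included <- out$par > 0L
  out$par <- NULL
  rownames(out) <- NULL
  out
}
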