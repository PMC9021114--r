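# Fixed-effects aggregation across datasets: pooled correlations,
# two-stage WLS estimation, multi-dataset equality-constrained GGMs, and
# the partial-pruning search.

check_aligned <- function(datasets) {
  datasets <- lapply(datasets, as_correlation_data)
  if (length(datasets) < 1L) stop("need at least one dataset")
  labs <- datasets[[1]]$labels
  for (d in datasets) {
    if (d$p != datasets[[1]]$p || !identical(d$labels, labs))
      stop("all datasets must share the same variables in the same order")
  }
  datasets
}

#' Pooled maximum likelihood correlations across datasets
#'
#' Estimates a single population correlation matrix underlying several
#' independent datasets by maximizing the sample-size weighted sum of
#' standardized Gaussian fit functions, with all dataset correlation
#' vectors constrained equal. Returns the pooled estimates together with
#' their unit Fisher information and parameter covariance matrix, the
#' inputs needed by the stage-2 weighted least squares network fit.
#'
#' @param datasets List of [correlation_data()] objects sharing variables.
#' @param control Passed to [fit_ml()].
#' @return An object of class `pooled_corr`: list with `rho`, `P`
#'   (pooled matrix), `information`, `vcov`, `n`, `k`, `fit`.
#' @export
pool_correlations <- function(datasets, control = list()) {
  datasets <- check_aligned(datasets)
  k <- length(datasets)
  p <- datasets[[1]]$p
  q <- p * (p - 1) / 2
  n <- sum(vapply(datasets, function(d) d$n, numeric(1)))
  pairs <- vechs_pairs(p)
  labs <- datasets[[1]]$labels

  pt <- do.call(rbind, lapply(seq_len(k), function(i) {
    new_par_table(group = i, mat = "rho",
                  row = pairs[, "i"], col = pairs[, "j"],
                  par = seq_len(q), fixed = 0,
                  label = paste0(labs[pairs[, "i"]], "--", labs[pairs[, "j"]]))
  }))
  groups <- lapply(seq_len(k), function(i) {
    corr_group(datasets[[i]], rows = (i - 1L) * q + seq_len(q),
               weight = datasets[[i]]$n / n)
  })
  Rbar <- Reduce(`+`, lapply(datasets, function(d) (d$n / n) * d$R))
  start <- vechs(Rbar)
  if (is.null(tryCatch(chol(vechs_to_matrix(start, p, 1)),
                       error = function(e) NULL)))
    start <- start * 0.9
  sat_F <- sum(vapply(datasets, function(d) (d$n / n) * saturated_F(d),
                      numeric(1)))
  spec <- list(pt = pt, groups = groups, n = n, k = k, sat_F = sat_F,
               likelihood = TRUE, ll_const = p * log(2 * pi),
               start = start, label = "Pooled correlations",
               datasets = datasets, model = "pooled_corr")
  fit <- fit_ml(spec, control = control)
  P <- vechs_to_matrix(fit$psi, p, diag_value = 1)
  dimnames(P) <- list(labs, labs)
  structure(list(rho = fit$psi, P = P, information = fit$information,
                 vcov = fit$vcov, n = n, k = k, fit = fit,
                 labels = labs),
            class = "pooled_corr")
}

#' @export
print.pooled_corr <- function(x, ...) {
  cat(sprintf("Pooled correlations over %d dataset(s), total n = %d\n",
              x$k, x$n))
  print(round(x$P, 3))
  invisible(x)
}

#' Two-stage fixed-effects network aggregation
#'
#' Stage 1 estimates pooled correlations and their Fisher information
#' with [pool_correlations()]; stage 2 fits the (possibly constrained)
#' partial-correlation network to the pooled correlations by weighted
#' least squares with the Fisher information as the weight matrix. For a
#' saturated network this reproduces the multi-dataset equality
#' constrained estimates and standard errors exactly.
#'
#' @param datasets List of [correlation_data()] objects sharing variables.
#' @param pattern Optional edge-inclusion pattern (see [ggm_fit()]).
#' @param weights `"fisher"` (full Fisher information, default), `"dwls"`
#'   (its diagonal) or `"uls"` (identity).
#' @param control Passed to [fit_ml()].
#' @return A `ggm_fit` (single WLS group over the pooled correlations)
#'   with the stage-1 result attached as attribute `stage1`.
#' @export
two_stage_fixed <- function(datasets, pattern = NULL,
                            weights = c("fisher", "dwls", "uls"),
                            control = list()) {
  weights <- match.arg(weights)
  stage1 <- pool_correlations(datasets, control = control)
  p <- nrow(stage1$P)
  q <- p * (p - 1) / 2
  W <- switch(weights,
              fisher = stage1$information,
              dwls = diag(diag(stage1$information), q),
              uls = diag(q))
  if (is.null(tryCatch(chol(W), error = function(e) NULL)))
    stop("stage-2 weight matrix is not positive definite")
  z <- stage1$rho

  pat <- normalize_pattern(pattern, p)
  pairs <- vechs_pairs(p)
  par <- integer(q)
  par[pat] <- seq_len(sum(pat))
  labs <- stage1$labels
  pt <- new_par_table(group = 1L, mat = "omega",
                      row = pairs[, "i"], col = pairs[, "j"],
                      par = par, fixed = 0,
                      label = paste0(labs[pairs[, "i"]], "--",
                                     labs[pairs[, "j"]]))
  group <- list(
    rows = seq_len(q),
    model = function(th, shared) {
      P <- ggm_implied(vechs_to_matrix(th, p))
      if (is.null(P)) NULL else vechs(P)
    },
    model_jac = function(th, shared) ggm_model_jacobian(vechs_to_matrix(th, p)),
    dist_fit = function(phi) wls_fit(z, phi, W),
    dist_jac = function(phi) wls_jacobian(z, phi, W),
    dist_hess = function(phi) wls_hessian(W),
    weight = 1, nphi = q
  )
  omega0 <- vechs(corr_to_ggm(stage1$P))
  omega0[!pat] <- 0
  omega0 <- admissible_start(omega0, p)
  spec <- list(pt = pt, groups = list(group), n = stage1$n, k = 1L,
               sat_F = 0, likelihood = FALSE, ll_const = 0,
               start = omega0[pat],
               label = "Two-stage fixed-effects GGM",
               datasets = check_aligned(datasets), model = "two_stage")
  fit <- fit_ml(spec, control = control)
  attr(fit, "stage1") <- stage1
  fit
}

# Build the parameter table for a multi-dataset GGM from a per-edge
# status vector: "pooled" (one parameter shared by all groups), "unique"
# (one parameter per group), "excluded" (fixed to zero everywhere).
multigroup_par_table <- function(edge_spec, p, k, labels) {
  q <- p * (p - 1) / 2
  stopifnot(length(edge_spec) == q)
  pairs <- vechs_pairs(p)
  par_mat <- matrix(0L, q, k)
  next_id <- 0L
  for (e in seq_len(q)) {
    if (edge_spec[e] == "pooled") {
      next_id <- next_id + 1L
      par_mat[e, ] <- next_id
    } else if (edge_spec[e] == "unique") {
      par_mat[e, ] <- next_id + seq_len(k)
      next_id <- next_id + k
    } else if (edge_spec[e] != "excluded") {
      stop("edge_spec entries must be 'pooled', 'unique' or 'excluded'")
    }
  }
  pt <- do.call(rbind, lapply(seq_len(k), function(i) {
    new_par_table(group = i, mat = "omega",
                  row = pairs[, "i"], col = pairs[, "j"],
                  par = par_mat[, i], fixed = 0,
                  label = paste0(labels[pairs[, "i"]], "--",
                                 labels[pairs[, "j"]]))
  }))
  list(pt = pt, par_mat = par_mat)
}

#' Multi-dataset network estimation with equality constraints
#'
#' Fits one GGM per dataset inside a single likelihood (the sample-size
#' weighted sum of per-dataset fit functions) while constraining edges
#' across datasets: each edge can be pooled (equal across datasets),
#' unique per dataset, or excluded everywhere. A fully pooled saturated
#' specification gives the fixed-effects aggregate network; a fully
#' unique specification reproduces separate single-dataset fits.
#'
#' @param datasets List of [correlation_data()] objects sharing variables.
#' @param edge_spec Either a single string (`"pooled"` or `"unique"`)
#'   applied to all edges, or a character vector of length p(p-1)/2 over
#'   `vechs` order with entries `"pooled"`, `"unique"`, `"excluded"`.
#' @param start Optional start vector for the free parameters.
#' @param control Passed to [fit_ml()].
#' @return A `ggm_fit`; per-group networks via `omega_matrix(fit, group)`.
#' @export
multidataset_ggm <- function(datasets, edge_spec = "pooled", start = NULL,
                             control = list()) {
  datasets <- check_aligned(datasets)
  k <- length(datasets)
  p <- datasets[[1]]$p
  q <- p * (p - 1) / 2
  if (length(edge_spec) == 1L) edge_spec <- rep(edge_spec, q)
  n <- sum(vapply(datasets, function(d) d$n, numeric(1)))
  tab <- multigroup_par_table(edge_spec, p, k, datasets[[1]]$labels)
  groups <- lapply(seq_len(k), function(i) {
    ggm_group(datasets[[i]], rows = (i - 1L) * q + seq_len(q),
              weight = datasets[[i]]$n / n)
  })
  sat_F <- sum(vapply(datasets, function(d) (d$n / n) * saturated_F(d),
                      numeric(1)))
  spec <- list(pt = tab$pt, groups = groups, n = n, k = k, sat_F = sat_F,
               likelihood = TRUE, ll_const = p * log(2 * pi),
               start = start, label = "Multi-dataset GGM",
               datasets = datasets, model = "multidataset",
               edge_spec = edge_spec)
  if (is.null(start)) spec$start <- multigroup_start(spec, datasets, tab$par_mat)
  fit_ml(spec, control = control)
}

multigroup_start <- function(spec, datasets, par_mat) {
  p <- datasets[[1]]$p
  k <- length(datasets)
  n <- spec$n
  Rbar <- Reduce(`+`, lapply(datasets, function(d) (d$n / n) * d$R))
  pooled_omega <- admissible_start(vechs(corr_to_ggm(Rbar)), p)
  per_group <- lapply(datasets, function(d)
    admissible_start(vechs(corr_to_ggm(d$R)), p))
  npar <- max(par_mat)
  start <- numeric(npar)
  for (e in seq_len(nrow(par_mat))) {
    ids <- par_mat[e, ]
    if (all(ids == 0L)) next
    if (length(unique(ids[ids > 0L])) == 1L) {
      start[ids[1]] <- pooled_omega[e]
    } else {
      for (i in seq_len(k)) if (ids[i] > 0L) start[ids[i]] <- per_group[[i]][e]
    }
  }
  start
}

#' Fixed-effects meta-analytic network estimation
#'
#' Convenience wrapper estimating a single pooled partial-correlation
#' network across datasets, by either the two-stage weighted least
#' squares route or the multi-dataset equality-constrained likelihood,
#' optionally followed by Wald significance pruning at level `alpha`.
#'
#' @param datasets List of [correlation_data()] objects sharing variables.
#' @param method `"two_stage"` or `"multidataset"`.
#' @param prune Prune non-significant edges after the saturated fit?
#' @param alpha Pruning significance level.
#' @param control Passed to [fit_ml()].
#' @return A `ggm_fit`.
#' @export
fixed_effects_ggm <- function(datasets, method = c("two_stage", "multidataset"),
                              prune = TRUE, alpha = 0.05, control = list()) {
  method <- match.arg(method)
  fit <- if (method == "two_stage") {
    two_stage_fixed(datasets, control = control)
  } else {
    multidataset_ggm(datasets, edge_spec = "pooled", control = control)
  }
  if (prune) fit <- prune(fit, alpha = alpha, control = control)
  fit
}

#' Partial pruning: exploratory search for cross-dataset differences
#'
#' Four-step search for a partially pooled network across datasets:
#' (1) estimate a significance-pruned network for each dataset
#' separately; (2) fit a pooled multi-dataset model including every edge
#' retained in at least one per-dataset network, all edges constrained
#' equal across datasets; (3) stepwise, compute modification indices for
#' the equality-constrained edges, sum them per edge across datasets,
#' and free the edge with the largest summed index (one parameter per
#' dataset) whenever this improves BIC, repeating until BIC no longer
#' improves; (4) remove all edge weights not significant at `alpha` and
#' refit the final model.
#'
#' @param datasets List of at least two [correlation_data()] objects.
#' @param alpha Significance level for the per-dataset and final pruning.
#' @param max_steps Cap on step-3 freeing iterations.
#' @param control Passed to [fit_ml()].
#' @return A list of class `partial_prune`: `fit` (final `ggm_fit`),
#'   `edge_spec` (per-edge status after the search), `freed` (labels of
#'   edges freed across datasets), `pooled_fit` (the step-2 model),
#'   `per_dataset` (step-1 pruned fits).
#' @export
partial_prune <- function(datasets, alpha = 0.05, max_steps = 30L,
                          control = list()) {
  datasets <- check_aligned(datasets)
  k <- length(datasets)
  if (k < 2L) stop("partial pruning requires at least two datasets")
  p <- datasets[[1]]$p
  q <- p * (p - 1) / 2

  # Step 1: per-dataset pruned models
  per_dataset <- lapply(datasets, function(d)
    prune(ggm_fit(d, control = control), alpha = alpha, control = control))
  included <- vapply(per_dataset, function(f) {
    pt <- f$par_table
    pt$par[pt$mat == "omega"] > 0L
  }, logical(q))
  union_edges <- apply(included, 1L, any)

  # Step 2: pooled model over the union of included edges
  edge_spec <- ifelse(union_edges, "pooled", "excluded")
  fit <- multidataset_ggm(datasets, edge_spec = edge_spec, control = control)
  pooled_fit <- fit

  # Step 3: stepwise freeing by summed modification index, accept on BIC
  freed <- character(0)
  for (step in seq_len(max_steps)) {
    mi <- modification_indices(fit, matrices = "omega")
    mi <- mi[mi$type == "equality", , drop = FALSE]
    if (nrow(mi) == 0L) break
    key <- paste(mi$row, mi$col)
    summed <- tapply(mi$mi, key, sum, na.rm = TRUE)
    best <- names(summed)[which.max(summed)]
    rc <- as.integer(strsplit(best, " ")[[1]])
    e <- which(vechs_pairs(p)[, "i"] == rc[1] & vechs_pairs(p)[, "j"] == rc[2])
    edge_spec_new <- edge_spec
    edge_spec_new[e] <- "unique"
    fit_new <- multidataset_ggm(datasets, edge_spec = edge_spec_new,
                                control = control)
    if (is.finite(fit_new$BIC) && fit_new$BIC < fit$BIC) {
      edge_spec <- edge_spec_new
      fit <- fit_new
      freed <- c(freed, fit$par_table$label[fit$par_table$group == 1L &
                                              fit$par_table$mat == "omega"][e])
    } else break
  }

  # Step 4: final significance pruning
  fit <- prune(fit, alpha = alpha, control = control)

  structure(list(fit = fit, edge_spec = edge_spec, freed = freed,
                 pooled_fit = pooled_fit, per_dataset = per_dataset,
                 alpha = alpha),
            class = "partial_prune")
}

#' @export
print.partial_prune <- function(x, ...) {
  cat("Partial pruning result\n")
  cat(sprintf("  %d edge(s) freed across datasets: %s\n",
              length(x$freed),
              if (length(x$freed)) paste(x$freed, collapse = ", ") else "none"))
  print(x$fit)
  invisible(x)
}
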