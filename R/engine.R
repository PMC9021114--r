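# General estimation engine.
#
# Every model in the package is expressed as: free parameters psi ->
# model parameters theta (through a sparse 0/1 "manual Jacobian" that
# encodes fixed values and equality constraints) -> distribution
# parameters phi (through a model map with analytic Jacobian) -> fit
# value (a -2/n log-likelihood style discrepancy with analytic Jacobian
# and expected Hessian). The engine below only manipulates these pieces;
# the model-specific content lives in the spec constructors.

# ---- parameter table ------------------------------------------------------

new_par_table <- function(group, mat, row, col, par, fixed, label = NA_character_) {
  data.frame(group = as.integer(group), mat = as.character(mat),
             row = as.integer(row), col = as.integer(col),
             par = as.integer(par), fixed = as.numeric(fixed),
             label = label, stringsAsFactors = FALSE)
}

n_free <- function(pt) {
  if (all(pt$par == 0L)) 0L else max(pt$par)
}

theta_vector <- function(pt, psi) {
  th <- pt$fixed
  free <- pt$par > 0L
  th[free] <- psi[pt$par[free]]
  th
}

manual_jacobian_matrix <- function(pt) {
  free <- which(pt$par > 0L)
  Matrix::sparseMatrix(i = free, j = pt$par[free], x = 1,
                       dims = c(nrow(pt), n_free(pt)))
}

# Renumber free parameters consecutively after rows have been fixed.
renumber_par_table <- function(pt) {
  ids <- sort(unique(pt$par[pt$par > 0L]))
  pt$par <- ifelse(pt$par > 0L, match(pt$par, ids), 0L)
  pt$par[is.na(pt$par)] <- 0L
  pt
}

# ---- engine evaluations ---------------------------------------------------

eng_prepare <- function(spec, th) {
  if (is.null(spec$prepare)) return(list(ok = TRUE, shared = NULL))
  shared <- spec$prepare(th)
  list(ok = !is.null(shared), shared = shared)
}

eng_value <- function(spec, psi) {
  th <- theta_vector(spec$pt, psi)
  prep <- eng_prepare(spec, th)
  if (!prep$ok) return(Inf)
  total <- 0
  for (g in spec$groups) {
    phi <- g$model(th[g$rows], prep$shared)
    if (is.null(phi)) return(Inf)
    f <- tryCatch(g$dist_fit(phi), error = function(e) Inf)
    if (!is.finite(f)) return(Inf)
    total <- total + g$weight * f
  }
  total
}

# Returns list(g_psi, g_theta) or NULL when the point is inadmissible.
eng_gradient <- function(spec, psi) {
  th <- theta_vector(spec$pt, psi)
  prep <- eng_prepare(spec, th)
  if (!prep$ok) return(NULL)
  g_theta <- numeric(nrow(spec$pt))
  for (g in spec$groups) {
    th_g <- th[g$rows]
    phi <- g$model(th_g, prep$shared)
    if (is.null(phi)) return(NULL)
    jd <- g$dist_jac(phi)
    jm <- g$model_jac(th_g, prep$shared)
    # accumulate: groups may share model-parameter rows (e.g. per-study
    # likelihood contributions to one common parameter block)
    g_theta[g$rows] <- g_theta[g$rows] + g$weight * as.numeric(jd %*% jm)
  }
  M <- manual_jacobian_matrix(spec$pt)
  list(g_psi = as.numeric(Matrix::crossprod(M, g_theta)), g_theta = g_theta)
}

# Unit Fisher information of the free parameters (Eq.-(5)-style chain
# rule), optionally retaining the per-group theta-level blocks needed for
# modification indices.
eng_fisher <- function(spec, psi, keep_blocks = FALSE) {
  th <- theta_vector(spec$pt, psi)
  prep <- eng_prepare(spec, th)
  if (!prep$ok) stop("cannot evaluate Fisher information at an inadmissible point")
  M <- manual_jacobian_matrix(spec$pt)
  npar <- ncol(M)
  I_psi <- matrix(0, npar, npar)
  blocks <- if (keep_blocks) vector("list", length(spec$groups)) else NULL
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    th_g <- th[g$rows]
    phi <- g$model(th_g, prep$shared)
    if (is.null(phi)) stop("inadmissible point in Fisher information")
    jm <- g$model_jac(th_g, prep$shared)
    H <- g$dist_hess(phi)
    B <- 0.5 * g$weight * crossprod(jm, H %*% jm)
    Mg <- M[g$rows, , drop = FALSE]
    I_psi <- I_psi + as.matrix(Matrix::crossprod(Mg, B %*% Mg))
    if (keep_blocks) blocks[[gi]] <- B
  }
  I_psi <- (I_psi + t(I_psi)) / 2
  list(I_psi = I_psi, blocks = blocks, M = M)
}

default_control <- function(control = list()) {
  utils::modifyList(list(grad_tol = 1e-5, iter_max = 1000L,
                         eval_max = 4000L, rel_tol = 1e-12,
                         restarts = 1L), control)
}

# ---- main fitter ----------------------------------------------------------

#' Fit a structured model by maximum likelihood
#'
#' Minimizes the model's fit function over its free parameters with a
#' quasi-Newton optimizer driven by the analytic chain-rule gradient,
#' then computes the Fisher information, parameter covariance matrix
#' (`vcov = solve(I) / n`), standard errors, Wald z statistics and
#' two-sided p values, and (where the model defines a saturated
#' comparison) chi-square, degrees of freedom, AIC, BIC and RMSEA.
#'
#' This is the workhorse behind [ggm_fit()], [pool_correlations()],
#' [fixed_effects_ggm()] and [fit_random_effects()]; it is exported for
#' programmatic use with specs built by those interfaces.
#'
#' @param spec An internal model specification (see the user-facing
#'   constructors).
#' @param start Optional numeric start vector for the free parameters.
#' @param control List of control values: `grad_tol` (maximum absolute
#'   gradient entry required to declare convergence, default 1e-5),
#'   `iter_max`, `eval_max`, `rel_tol`, `restarts`.
#' @return An object of class `ggm_fit`.
#' @export
fit_ml <- function(spec, start = NULL, control = list()) {
  ctrl <- default_control(control)
  npar <- n_free(spec$pt)
  if (is.null(start)) start <- spec$start
  if (is.null(start)) start <- numeric(npar)
  if (length(start) != npar) stop("start vector has wrong length")

  if (npar == 0L) {
    psi <- numeric(0)
    F_hat <- eng_value(spec, psi)
    return(finish_fit(spec, psi, F_hat, gradient = numeric(0),
                      converged = TRUE, iterations = 0L, ctrl = ctrl))
  }

  obj <- function(psi) eng_value(spec, psi)
  gr <- function(psi) {
    g <- eng_gradient(spec, psi)
    if (is.null(g)) rep(0, npar) else g$g_psi
  }
  if (!is.finite(obj(start)))
    stop("start values are outside the admissible region")

  res <- stats::nlminb(start, obj, gradient = gr,
                       control = list(iter.max = ctrl$iter_max,
                                      eval.max = ctrl$eval_max,
                                      rel.tol = ctrl$rel_tol))
  iterations <- res$iterations
  for (r in seq_len(ctrl$restarts)) {
    g <- eng_gradient(spec, res$par)
    if (!is.null(g) && max(abs(g$g_psi)) < ctrl$grad_tol) break
    res2 <- stats::nlminb(res$par, obj, gradient = gr,
                          control = list(iter.max = ctrl$iter_max,
                                         eval.max = ctrl$eval_max,
                                         rel.tol = ctrl$rel_tol))
    iterations <- iterations + res2$iterations
    if (res2$objective <= res$objective) res <- res2
  }

  psi <- res$par
  F_hat <- res$objective
  g <- eng_gradient(spec, psi)
  gradient <- if (is.null(g)) rep(NA_real_, npar) else g$g_psi
  gnorm <- if (is.null(g)) Inf else max(abs(gradient))
  converged <- is.finite(F_hat) && gnorm < ctrl$grad_tol
  finish_fit(spec, psi, F_hat, gradient, converged, iterations, ctrl)
}

finish_fit <- function(spec, psi, F_hat, gradient, converged, iterations, ctrl) {
  npar <- length(psi)
  fis <- if (npar > 0) eng_fisher(spec, psi) else list(I_psi = matrix(0, 0, 0))
  I_psi <- fis$I_psi
  V <- if (npar > 0) solve_information(I_psi, spec) / spec$n else matrix(0, 0, 0)
  se <- if (npar > 0) sqrt(pmax(diag(V), 0)) else numeric(0)
  z <- ifelse(se > 0, psi / se, NA_real_)
  pval <- 2 * stats::pnorm(-abs(z))
  pval[psi == 0 & se == 0] <- 1

  pt <- spec$pt
  free <- pt$par > 0L
  pt$est <- theta_vector(pt, psi)
  pt$se <- NA_real_; pt$z <- NA_real_; pt$p <- NA_real_
  pt$se[free] <- se[pt$par[free]]
  pt$z[free] <- z[pt$par[free]]
  pt$p[free] <- pval[pt$par[free]]

  nphi <- sum(vapply(spec$groups, function(g) g$nphi, numeric(1)))
  df <- nphi - npar
  chi2 <- AIC <- BIC <- rmsea <- NA_real_
  if (!is.null(spec$sat_F) && is.finite(spec$sat_F)) {
    chi2 <- max(0, spec$n * (F_hat - spec$sat_F))
    if (df > 0) {
      rmsea <- sqrt(spec$k) * sqrt(max(0, chi2 - df) / (df * spec$n))
    } else rmsea <- 0
  }
  if (isTRUE(spec$likelihood)) {
    # ll = -(n/2) (F + const), const = ln(2*pi) * sum(n_i p_i) / n
    ll <- -(spec$n / 2) * (F_hat + spec$ll_const)
    AIC <- -2 * ll + 2 * npar
    BIC <- -2 * ll + npar * log(spec$n)
  }

  structure(list(spec = spec, psi = psi, par_table = pt,
                 F_value = F_hat, gradient = gradient,
                 gradient_norm = if (npar > 0) max(abs(gradient)) else 0,
                 converged = converged, iterations = iterations,
                 information = I_psi, vcov = V, se = se, z = z,
                 p_values = pval, n = spec$n, k = spec$k,
                 npar = npar, nphi = nphi, df = df, chi2 = chi2,
                 AIC = AIC, BIC = BIC, rmsea = rmsea,
                 control = ctrl),
            class = "ggm_fit")
}

solve_information <- function(I_psi, spec) {
  inv <- tryCatch(chol2inv(chol(I_psi)), error = function(e) NULL)
  if (is.null(inv) && isTRUE(spec$pinv_information)) {
    # High-dimensional heterogeneity blocks (few studies, many Cholesky
    # parameters) routinely leave the information rank-deficient; the
    # pseudoinverse keeps the identified sub-block usable.
    inv <- MASS::ginv(I_psi)
  }
  if (is.null(inv)) {
    ev <- eigen(I_psi, symmetric = TRUE)
    bad <- which(ev$values < max(ev$values) * 1e-10)
    culprits <- unique(unlist(lapply(bad, function(b) {
      which(abs(ev$vectors[, b]) > 0.3)
    })))
    stop("Fisher information is singular; non-identified free parameters: ",
         paste(culprits, collapse = ", "))
  }
  (inv + t(inv)) / 2
}

# ---- accessors ------------------------------------------------------------

#' Inference quantities of a fitted model
#'
#' `fisher_information()` returns the unit Fisher information of the free
#' parameters, `param_covariance()` the estimated covariance matrix of
#' the ML estimator (`solve(I) / n`), and `wald_tests()` a table of
#' estimates, standard errors, z statistics and two-sided p values.
#'
#' @param fit A `ggm_fit` object.
#' @return A matrix (`fisher_information`, `param_covariance`) or a
#'   data frame (`wald_tests`).
#' @export
fisher_information <- function(fit) fit$information

#' @rdname fisher_information
#' @export
param_covariance <- function(fit) fit$vcov

#' @rdname fisher_information
#' @export
wald_tests <- function(fit) {
  data.frame(par = seq_along(fit$psi), est = fit$psi, se = fit$se,
             z = fit$z, p = fit$p_values)
}

#' @export
coef.ggm_fit <- function(object, ...) object$psi

#' @export
vcov.ggm_fit <- function(object, ...) object$vcov

#' @export
logLik.ggm_fit <- function(object, ...) {
  if (!isTRUE(object$spec$likelihood)) return(NA_real_)
  val <- -(object$n / 2) * (object$F_value + object$spec$ll_const)
  structure(val, df = object$npar, nobs = object$n, class = "logLik")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d free parameter(s), %d group(s), n = %d\n",
              if (!is.null(x$spec$label)) x$spec$label else "Model",
              x$npar, x$k, x$n))
  cat(sprintf("  F = %.6f, max|gradient| = %.2e, converged: %s\n",
              x$F_value, x$gradient_norm, x$converged))
  if (is.finite(x$chi2))
    cat(sprintf("  chi2 = %.3f on df = %d, RMSEA = %.4f\n",
                x$chi2, x$df, x$rmsea))
  if (is.finite(x$AIC))
    cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$AIC, x$BIC))
  invisible(x)
}

#' Fit indices and likelihood-ratio tests
#'
#' `fit_indices()` summarizes a fitted model's chi-square against its
#' saturated comparison, degrees of freedom, AIC, BIC and RMSEA.
#' `lrt()` compares two nested fits of the same data:
#' `stat = n (F_constrained - F_full)` on `df` equal to the difference in
#' free parameters.
#'
#' @param fit,fit_a,fit_b `ggm_fit` objects; for `lrt` the two fits must
#'   model the same data (`fit_a` the more constrained model).
#' @return `fit_indices()`: a one-row data frame; `lrt()`: a list with
#'   `statistic`, `df`, `p`.
#' @export
fit_indices <- function(fit) {
  data.frame(chi2 = fit$chi2, df = fit$df, AIC = fit$AIC, BIC = fit$BIC,
             rmsea = fit$rmsea)
}

#' @rdname fit_indices
#' @export
lrt <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n || fit_a$nphi != fit_b$nphi)
    stop("lrt() requires nested fits of the same data")
  if (fit_a$npar > fit_b$npar) { tmp <- fit_a; fit_a <- fit_b; fit_b <- tmp }
  stat <- fit_a$n * (fit_a$F_value - fit_b$F_value)
  df <- fit_b$npar - fit_a$npar
  if (df < 0 || stat < -1e-6)
    stop("lrt() requires nested fits (non-nested comparison)")
  stat <- max(0, stat)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- pruning --------------------------------------------------------------

#' Significance pruning of network edges
#'
#' Removes, simultaneously, every prunable free parameter whose Wald test
#' is non-significant at level `alpha` (fixing it to zero) and refits the
#' model once. Prunable parameters are edge weights (and, for saturated
#' correlation models, correlations); heterogeneity (Cholesky) parameters
#' are never pruned. With `recursive = TRUE` the removal-and-refit cycle
#' repeats until no further parameter can be removed.
#'
#' @param fit A converged `ggm_fit`.
#' @param alpha Significance level (default 0.05).
#' @param recursive Repeat pruning until stable? Default single pass.
#' @param control Passed to [fit_ml()].
#' @return A refitted `ggm_fit`; an empty model (all edges removed) is a
#'   valid outcome.
#' @export
prune <- function(fit, alpha = 0.05, recursive = FALSE, control = list()) {
  repeat {
    pt <- fit$par_table
    prunable <- pt$mat %in% c("omega", "rho") & pt$par > 0L
    ids <- unique(pt$par[prunable])
    pvals <- fit$p_values[ids]
    drop_ids <- ids[is.na(pvals) | pvals >= alpha]
    if (length(drop_ids) == 0L) return(fit)
    spec <- fit$spec
    keep_start <- fit$psi
    pt2 <- spec$pt
    sel <- pt2$par %in% drop_ids
    pt2$par[sel] <- 0L
    pt2$fixed[sel] <- 0
    pt2 <- renumber_par_table(pt2)
    spec$pt <- pt2
    kept <- setdiff(sort(unique(fit$spec$pt$par[fit$spec$pt$par > 0L])), drop_ids)
    spec$start <- keep_start[kept]
    fit <- fit_ml(spec, control = control)
    if (!recursive) return(fit)
  }
}

# ---- modification indices -------------------------------------------------

#' Modification indices for constrained parameters
#'
#' Univariate score (Lagrange multiplier) statistics estimating the
#' chi-square improvement from freeing one constrained model parameter:
#' either a parameter fixed to a value (e.g. an excluded edge) or one
#' element of an equality-constrained set (freeing that element in its
#' group while the rest of the set stays tied). For candidate row t with
#' fit-function gradient g_t and Fisher information partialled for the
#' current free parameters I_t, the index is `n g_t^2 / (4 I_t)`,
#' asymptotically chi-square with 1 df when the constraint holds.
#'
#' @param fit A converged `ggm_fit`.
#' @param matrices Which parameter matrices to consider (default
#'   `c("omega", "rho")`).
#' @return A data frame with one row per candidate (group, matrix
#'   element, constraint type, `mi`), sorted by decreasing `mi`. Empty
#'   for an all-free model.
#' @export
modification_indices <- function(fit, matrices = c("omega", "rho")) {
  spec <- fit$spec
  pt <- fit$par_table
  g <- eng_gradient(spec, fit$psi)
  if (is.null(g)) stop("cannot evaluate modification indices at an inadmissible point")
  fis <- eng_fisher(spec, fit$psi, keep_blocks = TRUE)
  M <- fis$M
  I_psi <- fis$I_psi
  I_inv <- tryCatch(chol2inv(chol(I_psi)), error = function(e) NULL)
  if (is.null(I_inv)) stop("Fisher information is singular")

  multiplicity <- tabulate(pt$par[pt$par > 0L], nbins = fit$npar)
  mult_row <- rep(0L, nrow(pt))
  mult_row[pt$par > 0L] <- multiplicity[pt$par[pt$par > 0L]]
  cand <- which(pt$mat %in% matrices & (pt$par == 0L | mult_row > 1L))
  if (length(cand) == 0L)
    return(data.frame(group = integer(0), mat = character(0),
                      row = integer(0), col = integer(0),
                      type = character(0), mi = numeric(0)))

  # Map each theta row to its group and local index for block lookup.
  row_group <- integer(nrow(pt)); row_local <- integer(nrow(pt))
  for (gi in seq_along(spec$groups)) {
    rows <- spec$groups[[gi]]$rows
    row_group[rows] <- gi
    row_local[rows] <- seq_along(rows)
  }

  mi <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    t_row <- cand[ci]
    gi <- row_group[t_row]
    B <- fis$blocks[[gi]]
    rows <- spec$groups[[gi]]$rows
    tl <- row_local[t_row]
    # column of I_theta for row t, projected to free parameters
    Mg <- M[rows, , drop = FALSE]
    c_vec <- as.numeric(Matrix::crossprod(Mg, B[, tl]))
    I_tt <- B[tl, tl]
    I_part <- I_tt - drop(crossprod(c_vec, I_inv %*% c_vec))
    mi[ci] <- if (I_part > 1e-12) {
      spec$n * g$g_theta[t_row]^2 / (4 * I_part)
    } else NA_real_
  }
  out <- data.frame(group = pt$group[cand], mat = pt$mat[cand],
                    row = pt$row[cand], col = pt$col[cand],
                    type = ifelse(pt$par[cand] == 0L, "fixed", "equality"),
                    par = pt$par[cand], theta_row = cand, mi = mi)
  out[order(-out$mi), ]
}
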