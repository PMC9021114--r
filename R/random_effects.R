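# Random-effects aggregation: study-level correlation vectors are
# modeled as Gaussian with mean equal to the GGM-implied correlations and
# covariance equal to known sampling variation plus a Cholesky
# parameterized heterogeneity component.

#' Assemble study-level correlation rows
#'
#' Builds the study-by-correlation data matrix used by random-effects
#' aggregation: one row per study holding its sample correlations in the
#' master `vechs` order, with `NA` at pairs involving variables the study
#' did not measure.
#'
#' @param datasets List of [correlation_data()] objects. Variable sets
#'   may differ across studies; the master variable list is the union in
#'   order of first appearance (or `labels` if given).
#' @param labels Optional master variable order.
#' @return An object of class `meta_rows`: list with `r` (k x q matrix,
#'   possibly containing `NA`), `n` (study sample sizes), `labels`,
#'   `study` (ids), `p`, `q`.
#' @export
build_rows <- function(datasets, labels = NULL) {
  datasets <- lapply(datasets, as_correlation_data)
  k <- length(datasets)
  if (is.null(labels)) {
    labels <- unique(unlist(lapply(datasets, function(d) d$labels)))
  }
  p <- length(labels)
  if (p < 2L) stop("need at least two master variables")
  pairs <- vechs_pairs(p)
  q <- nrow(pairs)
  r <- matrix(NA_real_, k, q)
  for (i in seq_len(k)) {
    d <- datasets[[i]]
    idx <- match(d$labels, labels)
    if (anyNA(idx)) stop("dataset ", i, " has variables outside the master list")
    if (length(idx) < 2L) stop("dataset ", i, " has fewer than 2 master variables")
    sub <- matrix(NA_real_, p, p)
    sub[idx, idx] <- d$R
    r[i, ] <- sub[cbind(pairs[, "i"], pairs[, "j"])]
  }
  colnames(r) <- paste0(labels[pairs[, "i"]], "--", labels[pairs[, "j"]])
  structure(list(r = r, n = vapply(datasets, function(d) d$n, numeric(1)),
                 labels = labels, study = seq_len(k), p = p, q = q),
            class = "meta_rows")
}

#' Estimate the sampling covariance of study correlations
#'
#' The asymptotic covariance of each study's sample correlation vector,
#' obtained from saturated correlation-model Fisher information. With
#' `method = "individual"` a separate estimate `V_i = vcov(rho_i)` is
#' formed per study (from that study's own saturated fit) and the
#' averaged matrix is their mean. With `method = "pooled"` a pooled
#' correlation model across all studies provides one estimate
#' `V* = k * vcov(rho_pooled)`, and per-study matrices are scaled as
#' `V_i = (nbar / n_i) V*` with `nbar = n / k`.
#'
#' @param datasets List of [correlation_data()] objects. For
#'   `"pooled"` all studies must share the full variable set.
#' @param method `"individual"` or `"pooled"`.
#' @param labels Optional master variable order (see [build_rows()]).
#' @return An object of class `sampling_cov`: list with `method`,
#'   `V_star` (q x q averaged matrix), `V_i` (list of q x q per-study
#'   matrices, `NA` outside a study's observed pairs), `nbar`.
#' @export
estimate_sampling_cov <- function(datasets, method = c("individual", "pooled"),
                                  labels = NULL) {
  method <- match.arg(method)
  datasets <- lapply(datasets, as_correlation_data)
  k <- length(datasets)
  rows <- build_rows(datasets, labels = labels)
  p <- rows$p; q <- rows$q
  pairs <- vechs_pairs(p)
  nbar <- sum(rows$n) / k

  if (method == "individual") {
    V_i <- vector("list", k)
    for (i in seq_len(k)) {
      d <- datasets[[i]]
      K <- tryCatch(sym_inverse(d$R, "study correlation matrix"),
                    error = function(e)
                      stop("study ", i, " is too small or singular for a ",
                           "saturated correlation fit"))
      sm <- structural_matrices(d$p)
      I_i <- as.matrix(Matrix::t(sm$Dstar) %*% (K %x% K) %*% sm$Dstar) / 2
      Vi_own <- solve(I_i) / d$n
      # embed into master pair order
      idx <- match(d$labels, rows$labels)
      own_pairs <- vechs_pairs(d$p)
      master_pos <- map_pairs_to_master(own_pairs, idx, p)
      V_full <- matrix(NA_real_, q, q)
      V_full[master_pos, master_pos] <- Vi_own
      V_i[[i]] <- V_full
    }
    obs_all <- vapply(V_i, function(V) !anyNA(diag(V)), logical(1))
    if (!any(obs_all))
      stop("no study observes the full variable set; cannot form V*")
    V_star <- Reduce(`+`, V_i[obs_all]) / sum(obs_all)
  } else {
    datasets_c <- check_aligned(datasets)
    stage1 <- pool_correlations(datasets_c)
    V_star <- k * stage1$vcov
    V_i <- lapply(seq_len(k), function(i) (nbar / rows$n[i]) * V_star)
  }
  structure(list(method = method, V_star = V_star, V_i = V_i, nbar = nbar,
                 q = q, labels = rows$labels),
            class = "sampling_cov")
}

# Positions in the master vechs order for each pair of a study's own
# vechs order, given the index map of its variables into the master list.
map_pairs_to_master <- function(own_pairs, idx, p_master) {
  a <- idx[own_pairs[, "i"]]
  b <- idx[own_pairs[, "j"]]
  i <- pmax(a, b); j <- pmin(a, b)
  # master vechs position of (i, j), i > j
  (j - 1L) * p_master - (j - 1L) * j / 2L + (i - j)
}

# vech positions in a q x q matrix for all pairs (a, b), a >= b, of an
# observed index subset (sorted increasing).
vech_subset_positions <- function(obs, q) {
  m <- length(obs)
  pos <- integer(m * (m + 1L) / 2L)
  t <- 0L
  for (b in seq_len(m)) {
    for (a in b:m) {
      t <- t + 1L
      jj <- obs[b]; ii <- obs[a]
      pos[t] <- (jj - 1L) * (q + 1L) - (jj - 1L) * jj / 2L + (ii - jj + 1L)
    }
  }
  pos
}

#' Random-effects meta-analytic network estimation
#'
#' Fits a common partial-correlation network to study-level correlation
#' vectors while modeling cross-study heterogeneity. Each study's
#' correlations are Gaussian with mean the GGM-implied correlations and
#' covariance `Sigma_i = V_i + T t(T)`, where `V_i` is the (known,
#' previously estimated) sampling covariance and `T t(T)` the
#' heterogeneity covariance, kept positive semi-definite through its
#' Cholesky factor `T`. Free parameters are the included edge weights
#' and all of `vech(T)`.
#'
#' Two estimation routes are available. `"averaged"` uses a single
#' covariance `Sigma = V* + T t(T)` for all studies and fits the mean
#' correlation vector and scatter matrix in one Gaussian likelihood;
#' it requires complete rows. `"per_study"` evaluates the likelihood
#' study by study with study-specific `Sigma_i`, and supports studies
#' with missing variables by subsetting the mean and covariance.
#'
#' @param rows A [build_rows()] object (or list of `correlation_data`).
#' @param sampling_cov A [estimate_sampling_cov()] result.
#' @param pattern Optional edge-inclusion pattern over the master
#'   variables (see [ggm_fit()]).
#' @param estimation `"averaged"` or `"per_study"`.
#' @param start_omega Optional start values for the edge weights; by
#'   default a pooled fixed-effects transform of the mean correlations.
#' @param start_t_diag Start value for the diagonal of `T` (default
#'   0.05; a small positive value avoids the boundary saddle at `T = 0`).
#' @param fix_tau Optional numeric vector of length q(q+1)/2 fixing the
#'   Cholesky parameters instead of estimating them; `fix_tau = 0`
#'   (recycled) fixes `T = 0`, reducing the model to a weighted
#'   fixed-effects fit with known sampling covariance.
#' @param control Passed to [fit_ml()]; the default gradient tolerance
#'   for these high-dimensional fits is 1e-3.
#' @return An object of class `c("re_fit", "ggm_fit")` with additional
#'   elements `T_hat`, `Sigma_ran` (= `T t(T)`), `re_sd`
#'   (`sqrt(diag(Sigma_ran))`, one per correlation pair) and `variant`.
#' @export
fit_random_effects <- function(rows, sampling_cov,
                               pattern = NULL,
                               estimation = c("averaged", "per_study"),
                               start_omega = NULL, start_t_diag = 0.05,
                               fix_tau = NULL, control = list()) {
  estimation <- match.arg(estimation)
  if (inherits(rows, "correlation_data") ||
      (is.list(rows) && !inherits(rows, "meta_rows") && is.null(rows$r)))
    rows <- build_rows(rows)
  k <- nrow(rows$r)
  if (k < 2L) stop("random-effects estimation requires at least two studies")
  p <- rows$p; q <- rows$q
  qt <- q * (q + 1L) / 2L
  pairs <- vechs_pairs(p)
  tau_pairs <- vech_pairs(q)
  control <- utils::modifyList(list(grad_tol = 1e-3), control)

  pat <- normalize_pattern(pattern, p)
  par_omega <- integer(q)
  par_omega[pat] <- seq_len(sum(pat))
  labs <- rows$labels
  pt_omega <- new_par_table(group = 1L, mat = "omega",
                            row = pairs[, "i"], col = pairs[, "j"],
                            par = par_omega, fixed = 0,
                            label = paste0(labs[pairs[, "i"]], "--",
                                           labs[pairs[, "j"]]))
  tau_free <- is.null(fix_tau)
  if (!tau_free) fix_tau <- rep_len(as.numeric(fix_tau), qt)
  pt_tau <- new_par_table(group = 1L, mat = "tau",
                          row = tau_pairs[, "i"], col = tau_pairs[, "j"],
                          par = if (tau_free) sum(pat) + seq_len(qt) else 0L,
                          fixed = if (tau_free) 0 else fix_tau,
                          label = paste0("tau[", tau_pairs[, "i"], ",",
                                         tau_pairs[, "j"], "]"))
  pt <- rbind(pt_omega, pt_tau)

  # Shared quantities per evaluated theta; groups read from this cache.
  cache <- new.env(parent = emptyenv())
  prepare <- function(th) {
    omega <- th[seq_len(q)]
    tau <- th[q + seq_len(qt)]
    P <- ggm_implied(vechs_to_matrix(omega, p))
    if (is.null(P)) return(NULL)
    T_mat <- vech_to_lower(tau, q)
    shared <- list(mu = vechs(P), T_mat = T_mat, TTt = tcrossprod(T_mat),
                   omega = omega)
    assign("shared", shared, envir = cache)
    shared
  }
  get_jacs <- function(th) {
    # memoised on theta: all per-study groups reuse one computation
    if (!is.null(cache$jac_th) && identical(cache$jac_th, th))
      return(cache$jacs)
    J_ggm <- ggm_model_jacobian(vechs_to_matrix(th[seq_len(q)], p))
    J_chol <- cholesky_model_jacobian(vech_to_lower(th[q + seq_len(qt)], q))
    cache$jac_th <- th
    cache$jacs <- list(J_ggm = J_ggm, J_chol = J_chol)
    cache$jacs
  }

  if (estimation == "averaged") {
    if (anyNA(rows$r))
      stop("averaged estimation requires complete rows; ",
           "use estimation = 'per_study' for studies with missing variables")
    rbar <- colMeans(rows$r)
    S <- crossprod(sweep(rows$r, 2, rbar)) / k
    V_star <- sampling_cov$V_star
    groups <- list(list(
      rows = seq_len(q + qt),
      model = function(th, shared) {
        Sigma <- V_star + shared$TTt
        if (is.null(tryCatch(chol(Sigma), error = function(e) NULL)))
          return(NULL)
        c(shared$mu, vech(Sigma))
      },
      model_jac = function(th, shared) {
        jacs <- get_jacs(th)
        blockdiag2(jacs$J_ggm, jacs$J_chol)
      },
      dist_fit = function(phi) {
        meta_gauss_fit(rbar, S, phi[seq_len(q)],
                       vech_to_matrix(phi[-seq_len(q)], q))
      },
      dist_jac = function(phi) {
        meta_gauss_jacobian(rbar, S, phi[seq_len(q)],
                            vech_to_matrix(phi[-seq_len(q)], q))
      },
      dist_hess = function(phi) {
        meta_gauss_hessian(vech_to_matrix(phi[-seq_len(q)], q))
      },
      weight = 1, nphi = q + qt
    ))
  } else {
    groups <- lapply(seq_len(k), function(i) {
      r_i <- rows$r[i, ]
      obs <- which(!is.na(r_i))
      m <- length(obs)
      sel <- vech_subset_positions(obs, q)
      V_i <- sampling_cov$V_i[[i]]
      V_i_obs <- V_i[obs, obs, drop = FALSE]
      if (anyNA(V_i_obs))
        stop("sampling covariance for study ", i,
             " is unavailable on its observed pairs")
      S0 <- matrix(0, m, m)
      list(
        rows = seq_len(q + qt),
        model = function(th, shared) {
          Sigma_i <- V_i_obs + shared$TTt[obs, obs, drop = FALSE]
          if (is.null(tryCatch(chol(Sigma_i), error = function(e) NULL)))
            return(NULL)
          c(shared$mu[obs], Sigma_i[lower.tri(Sigma_i, diag = TRUE)])
        },
        model_jac = function(th, shared) {
          jacs <- get_jacs(th)
          blockdiag2(jacs$J_ggm[obs, , drop = FALSE],
                     jacs$J_chol[sel, , drop = FALSE])
        },
        dist_fit = function(phi) {
          meta_gauss_fit(r_i[obs], S0, phi[seq_len(m)],
                         vech_to_matrix(phi[-seq_len(m)], m))
        },
        dist_jac = function(phi) {
          meta_gauss_jacobian(r_i[obs], S0, phi[seq_len(m)],
                              vech_to_matrix(phi[-seq_len(m)], m))
        },
        dist_hess = function(phi) {
          meta_gauss_hessian(vech_to_matrix(phi[-seq_len(m)], m))
        },
        weight = 1 / k, nphi = m + m * (m + 1) / 2
      )
    })
  }

  if (is.null(start_omega)) {
    rbar0 <- colMeans(rows$r, na.rm = TRUE)
    P0 <- vechs_to_matrix(rbar0, p, diag_value = 1)
    P0 <- nearest_pd_corr(P0)
    start_omega <- admissible_start(vechs(corr_to_ggm(P0)), p)
  }
  start_omega[!pat] <- 0
  start_tau <- numeric(qt)
  start_tau[tau_pairs[, "i"] == tau_pairs[, "j"]] <- start_t_diag
  start <- if (tau_free) c(start_omega[pat], start_tau) else start_omega[pat]

  spec <- list(pt = pt, groups = groups, n = k, k = 1L,
               sat_F = NA_real_, likelihood = FALSE, ll_const = 0,
               start = start, prepare = prepare,
               pinv_information = TRUE,
               label = sprintf("Random-effects GGM (%s, %s)",
                               sampling_cov$method, estimation),
               model = "random_effects", rows = rows,
               sampling_cov = sampling_cov, estimation = estimation)
  fit <- fit_ml(spec, control = control)
  decorate_re_fit(fit, q, qt, labs, pairs,
                  variant = c(sampling = sampling_cov$method,
                              estimation = estimation))
}

decorate_re_fit <- function(fit, q, qt, labs, pairs, variant) {
  pt <- fit$par_table
  tau_hat <- pt$est[pt$mat == "tau"]
  T_hat <- vech_to_lower(tau_hat, q)
  Sigma_ran <- tcrossprod(T_hat)
  re_sd <- sqrt(pmax(diag(Sigma_ran), 0))
  names(re_sd) <- paste0(labs[pairs[, "i"]], "--", labs[pairs[, "j"]])
  fit$T_hat <- T_hat
  fit$Sigma_ran <- Sigma_ran
  fit$re_sd <- re_sd
  fit$variant <- variant
  class(fit) <- c("re_fit", class(fit))
  fit
}

#' Prune a random-effects network fit
#'
#' Wald significance pruning of the edge weights only; the heterogeneity
#' (Cholesky) parameters are never pruned.
#'
#' @param fit An `re_fit` from [fit_random_effects()].
#' @param alpha Significance level.
#' @param control Passed to [fit_ml()].
#' @return A refitted `re_fit`.
#' @export
prune_random_effects <- function(fit, alpha = 0.05, control = list()) {
  control <- utils::modifyList(fit$control[c("grad_tol")], control)
  out <- prune(fit, alpha = alpha, control = control)
  pt <- out$par_table
  q <- sum(pt$mat == "omega")
  qt <- sum(pt$mat == "tau")
  p <- max(pt$row[pt$mat == "omega"])
  pairs <- vechs_pairs(p)
  labs <- fit$spec$rows$labels
  decorate_re_fit(out, q, qt, labs, pairs, variant = fit$variant)
}

# Block diagonal of two dense matrices.
blockdiag2 <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

# Project a symmetric matrix to a nearby positive definite correlation
# matrix (eigenvalue clipping + rescaling); used only for start values.
nearest_pd_corr <- function(M, eps = 1e-6) {
  if (!is.null(tryCatch(chol(M), error = function(e) NULL))) return(M)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, eps)
  M2 <- ev$vectors %*% diag(vals, length(vals)) %*% t(ev$vectors)
  D <- diag(1 / sqrt(diag(M2)), nrow(M2))
  D %*% M2 %*% D
}
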