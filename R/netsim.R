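# Synthetic-data generator and simulation harness: small-world true
# networks with diagonally dominant precision weighting, correlated
# random effects on the correlation scale, finite-sample correlation
# matrices, and recovery metrics.

#' Generate a true partial-correlation network
#'
#' Draws a small-world graph (ring lattice with `nei` neighbors on each
#' side, each edge rewired with probability `rewire_p`, no self loops or
#' duplicate edges, so the edge count p * nei is preserved), then weights
#' it through a diagonally dominant precision construction: nonzero
#' off-diagonal precision entries get magnitudes uniform on `par_range`,
#' the diagonal is `constant` times the absolute row sums (1 for
#' isolated nodes), and the standardized negative precision gives the
#' partial correlations. Signs are assigned so that `prop_positive` of
#' the resulting network edges are positive. The default settings yield
#' 16 edges (of 28 possible) for 8 nodes and 32 (of 120) for 16 nodes,
#' with mean absolute edge weight around 0.17.
#'
#' @param p Number of nodes (at least `2 * nei + 1`).
#' @param nei Neighbors on each side in the ring lattice (default 2,
#'   i.e. four nearest neighbors).
#' @param rewire_p Per-edge rewiring probability (default 0.25).
#' @param constant Diagonal dominance constant (default 1.5).
#' @param prop_positive Proportion of positive edges (default 0.9).
#' @param par_range Range of precision weight magnitudes (default
#'   `c(0.5, 1)`).
#' @return An object of class `true_network`: list with `omega` (hollow
#'   symmetric partial-correlation matrix), `adjacency` (logical),
#'   `P` (implied correlation matrix), `p`.
#' @export
generate_true_network <- function(p, nei = 2, rewire_p = 0.25,
                                  constant = 1.5, prop_positive = 0.9,
                                  par_range = c(0.5, 1)) {
  if (p < 2 * nei + 1)
    stop("p must be at least 2 * nei + 1 for the ring lattice")
  g <- igraph::sample_smallworld(dim = 1, size = p, nei = nei, p = rewire_p,
                                 loops = FALSE, multiple = FALSE)
  Adj <- as.matrix(igraph::as_adjacency_matrix(g))
  K <- matrix(0, p, p)
  up <- upper.tri(K)
  nz <- which(Adj[up] != 0)
  # negative precision entries map to positive partial correlations
  signs <- sample(c(-1, 1), length(nz), replace = TRUE,
                  prob = c(prop_positive, 1 - prop_positive))
  K[up][nz] <- signs * stats::runif(length(nz), par_range[1], par_range[2])
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  diag(K) <- constant * rowSums(abs(K))
  diag(K)[diag(K) == 0] <- 1
  d <- sqrt(diag(K))
  Omega <- -K / tcrossprod(d)
  diag(Omega) <- 0
  Omega <- (Omega + t(Omega)) / 2
  P <- ggm_to_corr(Omega)
  structure(list(omega = Omega, adjacency = Adj != 0, P = P, p = p),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  q <- x$p * (x$p - 1) / 2
  ne <- sum(x$omega[upper.tri(x$omega)] != 0)
  cat(sprintf("True network: %d nodes, %d of %d potential edges\n",
              x$p, ne, q))
  invisible(x)
}

#' Generate a random-effects covariance for correlations
#'
#' `Sigma_ran = re_sd^2 * C` with `C` a random correlation matrix drawn
#' by the C-vine construction (partial correlations from symmetric Beta
#' distributions chosen so the draw is uniform over the space of valid
#' correlation matrices). All correlation pairs share the same
#' random-effect standard deviation `re_sd`.
#'
#' @param q Dimension (number of correlation pairs).
#' @param re_sd Random-effect standard deviation (0 gives a zero matrix).
#' @return A q x q positive semi-definite covariance matrix.
#' @export
generate_re_cov <- function(q, re_sd) {
  if (re_sd < 0) stop("re_sd must be non-negative")
  if (re_sd == 0) return(matrix(0, q, q))
  re_sd^2 * rcorrmatrix_vine(q)
}

# Random correlation matrix, uniform over the elliptope (C-vine method
# with concentration 1).
rcorrmatrix_vine <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  Pp <- matrix(0, d, d)  # partial correlations
  S <- diag(d)
  for (kk in seq_len(d - 1)) {
    for (i in (kk + 1):d) {
      shape <- 1 + (d - 1 - kk) / 2
      pc <- 2 * stats::rbeta(1, shape, shape) - 1
      Pp[kk, i] <- pc
      r <- pc
      if (kk > 1) {
        for (l in (kk - 1):1) {
          r <- r * sqrt((1 - Pp[l, i]^2) * (1 - Pp[l, kk]^2)) + Pp[l, i] * Pp[l, kk]
        }
      }
      S[kk, i] <- r
      S[i, kk] <- r
    }
  }
  S
}

#' Simulate study-level correlation matrices from a true network
#'
#' For each of `k` studies: perturb the true implied correlations with a
#' draw from `N(0, re_cov)` (redrawing until the perturbed matrix is a
#' valid positive definite correlation matrix), draw a sample size
#' uniformly from `n_range`, sample that many standard Gaussian
#' observation vectors with the perturbed population correlation, and
#' return the sample correlation matrix.
#'
#' @param net A [generate_true_network()] object.
#' @param k Number of studies.
#' @param re_cov Optional q x q random-effects covariance (default no
#'   heterogeneity).
#' @param n_range Integer range of study sample sizes (default
#'   `c(250, 1000)`).
#' @param max_redraws Redraw budget for non-positive-definite
#'   perturbations before failing with advice to lower the
#'   random-effect SD.
#' @return A list of `k` [correlation_data()] objects.
#' @export
simulate_studies <- function(net, k, re_cov = NULL,
                             n_range = c(250, 1000), max_redraws = 1000) {
  p <- net$p
  q <- p * (p - 1) / 2
  rho_true <- vechs(net$P)
  if (is.null(re_cov)) re_cov <- matrix(0, q, q)
  if (nrow(re_cov) != q) stop("re_cov must be q x q with q = p(p-1)/2")
  homogeneous <- all(re_cov == 0)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    P_i <- NULL
    for (try in seq_len(max_redraws)) {
      rho_i <- rho_true
      if (!homogeneous)
        rho_i <- rho_i + as.numeric(MASS::mvrnorm(1, rep(0, q), re_cov))
      if (any(abs(rho_i) >= 1)) next
      cand <- vechs_to_matrix(rho_i, p, diag_value = 1)
      if (!is.null(tryCatch(chol(cand), error = function(e) NULL))) {
        P_i <- cand
        break
      }
      if (homogeneous) break
    }
    if (is.null(P_i))
      stop("could not draw a positive definite perturbed correlation matrix; ",
           "consider a smaller random-effect standard deviation")
    n_i <- if (n_range[1] == n_range[2]) {
      n_range[1]
    } else {
      sample(seq(n_range[1], n_range[2]), 1)
    }
    Y <- MASS::mvrnorm(n_i, rep(0, p), P_i)
    out[[i]] <- correlation_data(stats::cor(Y), n_i,
                                 labels = paste0("V", seq_len(p)))
  }
  out
}

#' Score an estimated network against the truth
#'
#' Edge-detection and weight-recovery metrics: sensitivity (share of
#' true edges present in the estimate), specificity (share of true
#' absent edges absent in the estimate), the Pearson correlation between
#' absolute true and absolute estimated weights over all potential
#' edges, and (when random-effect SDs are supplied) the mean absolute
#' deviation between estimated and true random-effect SDs.
#'
#' @param net A `true_network`.
#' @param omega_est Estimated partial-correlation matrix.
#' @param true_re_sd,est_re_sd Optional random-effect SDs (scalar or per
#'   pair) for the bias metric.
#' @return A one-row data frame with `sensitivity`, `specificity`,
#'   `correlation`, `re_bias` (NA when not applicable; sensitivity is NA
#'   for a truth without edges).
#' @export
evaluate_network <- function(net, omega_est, true_re_sd = NULL,
                             est_re_sd = NULL) {
  if (nrow(omega_est) != net$p) stop("dimension mismatch")
  w_true <- vechs(net$omega)
  w_est <- vechs(omega_est)
  true_edge <- w_true != 0
  est_edge <- w_est != 0
  tp <- sum(true_edge & est_edge)
  fn <- sum(true_edge & !est_edge)
  tn <- sum(!true_edge & !est_edge)
  fp <- sum(!true_edge & est_edge)
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  correlation <- if (stats::sd(abs(w_true)) > 0 && stats::sd(abs(w_est)) > 0) {
    stats::cor(abs(w_true), abs(w_est))
  } else NA_real_
  re_bias <- if (!is.null(true_re_sd) && !is.null(est_re_sd)) {
    mean(abs(est_re_sd - true_re_sd))
  } else NA_real_
  data.frame(sensitivity = sensitivity, specificity = specificity,
             correlation = correlation, re_bias = re_bias)
}

#' Run a simulation condition
#'
#' Replicates the full pipeline: generate a true network, draw a
#' random-effects covariance, simulate study correlation matrices, fit
#' the requested aggregation method with significance pruning, and score
#' recovery. Per-replication failures are recorded in the output rather
#' than raised.
#'
#' @param p Number of nodes.
#' @param k Number of studies.
#' @param re_sd Random-effect standard deviation (0, 0.05, 0.1, ...).
#' @param method One of `"fixed_two_stage"`, `"fixed_multidataset"`,
#'   `"re_individual_averaged"`, `"re_pooled_averaged"`,
#'   `"re_individual_per_study"`, `"re_pooled_per_study"`.
#' @param reps Number of replications.
#' @param alpha Pruning significance level.
#' @param n_range Study sample-size range.
#' @param seed Optional seed set once before the loop; the run is
#'   reproducible given (arguments, seed).
#' @param control Optimizer control passed through.
#' @return A long-format data frame, one row per replication, with the
#'   condition, the recovery metrics and an `error` column.
#' @export
run_study <- function(p = 8, k = 8, re_sd = 0, method = "fixed_two_stage",
                      reps = 10, alpha = 0.05, n_range = c(250, 1000),
                      seed = NULL, control = list()) {
  if (!is.null(seed)) set.seed(seed)
  q <- p * (p - 1) / 2
  res <- vector("list", reps)
  for (r in seq_len(reps)) {
    row <- data.frame(p = p, k = k, re_sd = re_sd, method = method, rep = r,
                      sensitivity = NA_real_, specificity = NA_real_,
                      correlation = NA_real_, re_bias = NA_real_,
                      error = NA_character_)
    metrics <- tryCatch({
      net <- generate_true_network(p)
      re_cov <- generate_re_cov(q, re_sd)
      studies <- simulate_studies(net, k = k, re_cov = re_cov,
                                  n_range = n_range)
      fit_and_score(net, studies, method, alpha, re_sd, control)
    }, error = function(e) e)
    if (inherits(metrics, "error")) {
      row$error <- conditionMessage(metrics)
    } else {
      row[names(metrics)] <- metrics
    }
    res[[r]] <- row
  }
  do.call(rbind, res)
}

fit_and_score <- function(net, studies, method, alpha, re_sd, control) {
  if (method %in% c("fixed_two_stage", "fixed_multidataset")) {
    fit <- fixed_effects_ggm(
      studies,
      method = sub("fixed_", "", method),
      prune = TRUE, alpha = alpha, control = control)
    evaluate_network(net, omega_matrix(fit))
  } else if (grepl("^re_", method)) {
    parts <- strsplit(sub("re_", "", method), "_", fixed = TRUE)[[1]]
    sampling <- parts[1]
    estimation <- paste(parts[-1], collapse = "_")
    sc <- estimate_sampling_cov(studies, method = sampling)
    fit <- fit_random_effects(build_rows(studies), sc,
                              estimation = estimation, control = control)
    fit <- prune_random_effects(fit, alpha = alpha, control = control)
    evaluate_network(net, omega_matrix(fit),
                     true_re_sd = re_sd, est_re_sd = fit$re_sd)
  } else {
    stop("unknown method: ", method)
  }
}
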