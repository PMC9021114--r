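# File input/output: correlation and raw-data CSV readers, result
# writers, and run manifests.

#' Read a correlation matrix from CSV
#'
#' Expects a square numeric CSV with a header row and a first column of
#' variable labels. Small asymmetries (beyond 1e-6) are symmetrized with
#' a warning; off-unit diagonals are reset to 1 with a warning.
#'
#' @param path Path to the CSV file.
#' @param n Sample size of the study (required; correlation input does
#'   not carry it).
#' @return A [correlation_data()] object.
#' @export
read_correlation_csv <- function(path, n) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(raw)
  if (!is.numeric(M)) stop("correlation CSV must be numeric: ", path)
  if (nrow(M) != ncol(M))
    stop("correlation CSV must be square: ", path,
         sprintf(" (%d x %d)", nrow(M), ncol(M)))
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("correlation CSV must carry variable labels: ", path)
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6)
    warning(sprintf("asymmetry of %.2g symmetrized in %s", asym, path))
  M <- (M + t(M)) / 2
  dd <- max(abs(diag(M) - 1))
  if (dd > 1e-6) {
    warning(sprintf("diagonal deviates from 1 by %.2g in %s; reset", dd, path))
  }
  diag(M) <- 1
  correlation_data(M, n, labels = rownames(M))
}

#' Read raw standardized data from CSV and form its correlation matrix
#'
#' Reads a complete numeric table (rows = cases, columns = variables),
#' standardizes each column to mean 0 and standard deviation 1 (with the
#' 1/n denominator), and returns `R = t(Y) Y / n` with `n` the row
#' count. Missing cells are not supported for raw input; supply a
#' correlation matrix instead.
#'
#' @param path Path to the CSV file.
#' @return A [correlation_data()] object.
#' @export
read_raw_csv <- function(path) {
  Y <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (!is.numeric(Y)) stop("raw data CSV must be numeric: ", path)
  if (anyNA(Y))
    stop("raw data CSV contains missing cells; case-level missingness is ",
         "not supported - compute and supply a correlation matrix instead")
  n <- nrow(Y)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  sds <- sqrt(colSums(Y^2) / n)
  if (any(sds == 0)) stop("constant column in raw data: ", path)
  Y <- sweep(Y, 2, sds, "/")
  R <- crossprod(Y) / n
  diag(R) <- 1
  correlation_data(R, n, labels = colnames(Y))
}

#' Read a run manifest
#'
#' A YAML manifest lists the studies (`studies:` with `id`,
#' `path`, `type` (`correlation` or `raw`), `n` for correlation input)
#' and an `analysis:` block (`mode`, `alpha`, `seed`, ...). Paths are
#' resolved relative to the manifest location.
#'
#' @param path Path to the YAML manifest.
#' @return A list with `datasets` (list of [correlation_data()]) and
#'   `analysis` (named list).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$studies) || length(m$studies) == 0L)
    stop("manifest has no studies")
  base <- dirname(normalizePath(path))
  datasets <- lapply(m$studies, function(s) {
    fp <- s$path
    if (!file.exists(fp)) fp <- file.path(base, s$path)
    if (!file.exists(fp)) stop("study file not found: ", s$path)
    type <- if (is.null(s$type)) "correlation" else s$type
    d <- if (type == "raw") {
      read_raw_csv(fp)
    } else {
      if (is.null(s$n)) stop("correlation input requires n for study ", s$id)
      read_correlation_csv(fp, n = s$n)
    }
    if (!is.null(s$variables)) {
      idx <- match(s$variables, d$labels)
      if (anyNA(idx)) stop("unknown variable subset for study ", s$id)
      d <- correlation_data(d$R[idx, idx], d$n, labels = d$labels[idx])
    }
    d
  })
  analysis <- if (is.null(m$analysis)) list() else m$analysis
  list(datasets = datasets, analysis = analysis)
}

#' Write fit results to a directory
#'
#' Writes an edge list CSV (per group: node pair, weight, SE, z, p,
#' inclusion), a weight-matrix CSV per group, a fit-index summary CSV,
#' a random-effect SD table for random-effects fits, and a JSON run log
#' echoing the configuration.
#'
#' @param fit A `ggm_fit` (or `re_fit`).
#' @param dir Output directory (created if absent).
#' @param config Optional named list echoed into the run log.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, dir, config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  et <- edge_table(fit)
  f <- file.path(dir, "edges.csv")
  utils::write.csv(et, f, row.names = FALSE)
  paths <- c(paths, f)

  for (g in unique(fit$par_table$group[fit$par_table$mat %in% c("omega", "rho")])) {
    pt <- fit$par_table
    sel <- pt$group == g & pt$mat %in% c("omega", "rho")
    block <- pt[sel, ]
    M <- vechs_to_matrix(block$est, max(block$row),
                         diag_value = if (block$mat[1] == "rho") 1 else 0)
    f <- file.path(dir, sprintf("weights_group%d.csv", g))
    utils::write.csv(M, f, row.names = FALSE)
    paths <- c(paths, f)
  }

  f <- file.path(dir, "fit_indices.csv")
  utils::write.csv(cbind(fit_indices(fit),
                         F_value = fit$F_value,
                         converged = fit$converged,
                         gradient_norm = fit$gradient_norm),
                   f, row.names = FALSE)
  paths <- c(paths, f)

  if (inherits(fit, "re_fit")) {
    f <- file.path(dir, "random_effect_sd.csv")
    utils::write.csv(data.frame(pair = names(fit$re_sd), re_sd = fit$re_sd),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }

  log <- list(package = "ggmeta",
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              n = fit$n, groups = fit$k, npar = fit$npar,
              converged = fit$converged, config = config)
  f <- file.path(dir, "run_log.yaml")
  yaml::write_yaml(log, f)
  paths <- c(paths, f)
  invisible(paths)
}
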