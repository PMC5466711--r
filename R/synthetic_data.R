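#' Simulation configuration for the three-level random-effects model
#'
#' Describes a synthetic serial-scanning study: `n_subjects` (K) participants
#' scanned in `n_sessions` (I) sessions under `n_conditions` (J) conditions,
#' with edge-level connectivity generated as
#' \deqn{y_{ijk} = \mu + \delta_k + \gamma_{jk} + \varepsilon_{ijk}}
#' where \eqn{\delta_k \sim N(0, \sigma_3^2)} is a subject effect,
#' \eqn{\gamma_{jk} \sim N(0, \sigma_2^2)} a subject-by-condition effect and
#' \eqn{\varepsilon_{ijk} \sim N(0, \sigma_0^2)} the session-level residual,
#' all mutually independent. Effects are generated in Fisher-z units.
#'
#' @param n_subjects,n_conditions,n_sessions Design dimensions (K >= 2,
#'   J >= 1, I >= 2).
#' @param n_edges Number of edges V for edge-level simulation.
#' @param n_rois Number of ROIs R for time-series simulation (V = R(R-1)/2).
#' @param mu Grand mean edge value, Fisher-z units.
#' @param sigma3_sq,sigma2_sq,sigma0_sq Nonnegative variance components:
#'   between subjects, between conditions within subject, between sessions
#'   (residual).
#' @param n_timepoints Time points per scan (time-series mode).
#' @param seed Root seed; all randomness derives from it.
#' @param missingness Optional data.frame of (subject, condition, session)
#'   cells to mask.
#' @param condition_labels,subject_ids Optional label vectors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10L, n_conditions = 4L, n_sessions = 12L,
                       n_edges = 1000L, n_rois = NULL,
                       mu = 0.3, sigma3_sq = 0.04, sigma2_sq = 0.01,
                       sigma0_sq = 0.10, n_timepoints = 414L, seed = 1L,
                       missingness = NULL,
                       condition_labels = NULL, subject_ids = NULL) {
  if (n_subjects < 2L) stop_fc("need at least 2 subjects")
  if (n_conditions < 1L) stop_fc("need at least 1 condition")
  if (n_sessions < 2L) stop_fc("need at least 2 sessions")
  if (min(sigma3_sq, sigma2_sq, sigma0_sq) < 0) {
    stop_fc("variance components must be nonnegative")
  }
  if (!is.null(n_rois)) {
    n_rois <- as.integer(n_rois)
    if (n_rois < 3L) stop_fc("time-series mode needs at least 3 ROIs")
    n_edges <- (n_rois * (n_rois - 1L)) %/% 2L
  }
  if (!is.null(missingness)) {
    missingness <- as.data.frame(missingness)
    if (any(missingness$subject > n_subjects |
            missingness$condition > n_conditions |
            missingness$session > n_sessions |
            unlist(missingness[c("subject", "condition", "session")]) < 1L)) {
      stop_fc("missingness cells out of bounds")
    }
  }
  cond_default <- c("rest", "inscapes", "movie", "flanker")
  condition_labels <- condition_labels %||%
    (if (n_conditions <= 4L) cond_default[seq_len(n_conditions)]
     else sprintf("cond%d", seq_len(n_conditions)))
  subject_ids <- subject_ids %||% sprintf("sub-%02d", seq_len(n_subjects))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_conditions = as.integer(n_conditions),
                 n_sessions = as.integer(n_sessions),
                 n_edges = as.integer(n_edges), n_rois = n_rois,
                 mu = mu, sigma3_sq = sigma3_sq, sigma2_sq = sigma2_sq,
                 sigma0_sq = sigma0_sq,
                 n_timepoints = as.integer(n_timepoints),
                 seed = as.integer(seed), missingness = missingness,
                 condition_labels = condition_labels,
                 subject_ids = subject_ids),
            class = "sim_config")
}

#' Simulate an edge-level observation panel with known ground truth
#'
#' Draws every edge independently from the three-level model described in
#' [sim_config()] and returns the panel together with the effect draws, so
#' downstream estimators can be checked against a recoverable truth.
#'
#' @param config A `sim_config`.
#' @return List with `panel` (an [edge_panel()] in Fisher-z units, mask set
#'   from `config$missingness`) and `truth` (list: `mu`, `delta` K x V,
#'   `gamma` K x J x V, `eps` K x J x I x V, and the configured variances).
#' @export
simulate_edge_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_subjects; J <- config$n_conditions
  I <- config$n_sessions; V <- config$n_edges
  draws <- with_local_seed(config$seed, {
    list(delta = matrix(stats::rnorm(K * V, 0, sqrt(config$sigma3_sq)), K, V),
         gamma = array(stats::rnorm(K * J * V, 0, sqrt(config$sigma2_sq)),
                       c(K, J, V)),
         eps = array(stats::rnorm(K * J * I * V, 0, sqrt(config$sigma0_sq)),
                     c(K, J, I, V)))
  })
  values <- config$mu + draws$eps +
    aperm(array(draws$delta, c(K, V, J, I)), c(1L, 3L, 4L, 2L)) +
    aperm(array(draws$gamma, c(K, J, V, I)), c(1L, 2L, 4L, 3L))
  dimnames(values) <- list(config$subject_ids, config$condition_labels,
                           sprintf("ses-%02d", seq_len(I)),
                           sprintf("edge%d", seq_len(V)))
  panel <- edge_panel(values, units = "fisher_z")
  if (!is.null(config$missingness)) {
    panel <- inject_missing(panel, config$missingness)
  }
  truth <- c(draws, list(mu = config$mu, sigma3_sq = config$sigma3_sq,
                         sigma2_sq = config$sigma2_sq,
                         sigma0_sq = config$sigma0_sq))
  list(panel = panel, truth = truth)
}

## Eigenvalue-clipped projection to a positive-definite correlation matrix:
## clip eigenvalues at `eps`, reconstruct, rescale to unit diagonal.
repair_correlation <- function(m, eps = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) {
    diag(m) <- 1
    return(m)
  }
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  (out + t(out)) / 2
}

#' Simulate per-scan ROI time series carrying the three-level edge structure
#'
#' For each (subject, condition, session) scan a target correlation matrix is
#' built by adding the scan's edge-level effect draws (Fisher-z units, from
#' the same model as [simulate_edge_panel()]) to a shared base matrix, mapping
#' back through `tanh`, and projecting to the nearest positive-definite
#' correlation matrix; a Gaussian T x R series is then sampled through the
#' Cholesky factor. Per-scan RNG streams are derived deterministically from
#' the root seed and the scan indices, so results do not depend on iteration
#' order.
#'
#' @param config A `sim_config` with `n_rois` set.
#' @param base_cor Optional R x R base correlation matrix (r units); defaults
#'   to an exchangeable matrix with off-diagonal `tanh(config$mu)`.
#' @return A `timeseries_panel`: list of scans, each with `data` (T x R
#'   matrix), `subject`, `condition`, `session`, and `target` (the repaired
#'   target correlation matrix); attributes carry the config and the truth
#'   draws.
#' @export
simulate_timeseries_panel <- function(config, base_cor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$n_rois)) stop_fc("config must set n_rois for time-series mode")
  if (config$n_timepoints < 50L) stop_fc("need at least 50 timepoints per scan")
  R <- config$n_rois; T_ <- config$n_timepoints
  K <- config$n_subjects; J <- config$n_conditions; I <- config$n_sessions
  if (is.null(base_cor)) {
    base_cor <- matrix(tanh(config$mu), R, R)
    diag(base_cor) <- 1
  }
  if (!identical(dim(base_cor), c(R, R))) stop_fc("base_cor must be %d x %d", R, R)
  ut <- upper.tri(base_cor)
  base_z <- atanh(base_cor[ut])

  edge_cfg <- config
  edge_cfg$missingness <- NULL
  sim <- simulate_edge_panel(edge_cfg)
  truth <- sim$truth

  roi_labels <- sprintf("roi%03d", seq_len(R))
  scans <- vector("list", K * J * I)
  s <- 0L
  for (k in seq_len(K)) for (j in seq_len(J)) for (i in seq_len(I)) {
    z <- base_z + truth$delta[k, ] + truth$gamma[k, j, ] + truth$eps[k, j, i, ]
    target <- diag(R)
    target[ut] <- tanh(z)
    target <- target + t(target) - diag(R)
    target <- repair_correlation(target)
    ch <- tryCatch(chol(target), error = function(e) NULL)
    if (is.null(ch)) {
      stop_fc("target correlation for scan (subject %d, condition %d, session %d) is not positive definite after repair",
              k, j, i)
    }
    x <- with_local_seed(derive_seed(config$seed, k, j, i), {
      matrix(stats::rnorm(T_ * R), T_, R) %*% ch
    })
    colnames(x) <- roi_labels
    s <- s + 1L
    scans[[s]] <- list(data = x,
                       subject = config$subject_ids[k],
                       condition = config$condition_labels[j],
                       session = i,
                       target = target)
  }
  structure(scans, class = "timeseries_panel",
            config = config, truth = truth, base_cor = base_cor,
            roi_labels = roi_labels)
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("timeseries_panel: %d scans (%d subjects x %d conditions x %d sessions), %d timepoints x %d ROIs\n",
              length(x), cfg$n_subjects, cfg$n_conditions, cfg$n_sessions,
              cfg$n_timepoints, cfg$n_rois))
  invisible(x)
}

#' Write a time-series panel as per-scan TSV files
#'
#' Files are named `sub-<K>_ses-<I>_task-<condition>_run-1_timeseries.tsv`
#' with a header row of ROI labels.
#'
#' @param tsp A `timeseries_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_timeseries_tsv <- function(tsp, dir) {
  stopifnot(inherits(tsp, "timeseries_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(tsp, function(scan) {
    fn <- sprintf("%s_ses-%02d_task-%s_run-1_timeseries.tsv",
                  scan$subject, scan$session, scan$condition)
    p <- file.path(dir, fn)
    utils::write.table(scan$data, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
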