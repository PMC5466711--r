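#' Expand six rigid-body motion parameters to the 24-regressor model
#'
#' Builds the standard 24-parameter motion confound set: the six parameters,
#' their squares, their backward temporal differences (first row zero), and
#' the squared differences. Column order is `p1..p6, p1^2..p6^2, d1..d6,
#' d1^2..d6^2`.
#'
#' @param params6 T x 6 numeric matrix of motion parameters.
#' @return T x 24 numeric matrix.
#' @export
build_motion_regressors <- function(params6) {
  params6 <- as.matrix(params6)
  if (ncol(params6) != 6L) stop_fc("expected 6 motion parameter columns, got %d", ncol(params6))
  if (nrow(params6) < 3L) stop_fc("need at least 3 timepoints")
  d <- rbind(0, diff(params6))
  out <- cbind(params6, params6^2, d, d^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("d", 1:6), paste0("d", 1:6, "_sq"))
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least squares of each ROI column on an intercept, orthogonal
#' polynomial trend columns up to `poly_order`, and any confound columns;
#' returns the residuals. Exactly collinear design columns are dropped (with
#' a warning naming them) before fitting.
#'
#' @param ts T x R numeric matrix of ROI time series.
#' @param confounds Optional T x C confound matrix (e.g. the output of
#'   [build_motion_regressors()], tissue mean signals).
#' @param poly_order Polynomial detrending order (0 = demean only).
#' @return T x R matrix of residuals (same dimnames as `ts`).
#' @export
nuisance_regress <- function(ts, confounds = NULL, poly_order = 2L) {
  ts <- as.matrix(ts)
  T_ <- nrow(ts)
  if (T_ < 10L) stop_fc("need at least 10 timepoints")
  if (any(!is.finite(ts))) stop_fc("time series contains non-finite values")
  design <- matrix(1, T_, 1L, dimnames = list(NULL, "intercept"))
  if (poly_order > 0L) {
    p <- stats::poly(seq_len(T_), degree = poly_order)
    colnames(p) <- paste0("poly", seq_len(poly_order))
    design <- cbind(design, p)
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T_) stop_fc("confounds must have %d rows", T_)
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    }
    design <- cbind(design, confounds)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning(sprintf("dropped exactly collinear design column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    design <- design[, sort(keep), drop = FALSE]
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design)) {
      stop_fc("design remains rank-deficient after dropping: %s",
              paste(dropped, collapse = ", "))
    }
  }
  res <- ts - design %*% qr.coef(qr_d, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Pairwise Pearson connectivity matrix from ROI time series
#'
#' @param ts T x R numeric matrix; each column must have nonzero variance.
#' @return R x R symmetric correlation matrix with unit diagonal (class
#'   `connectivity_matrix`, attribute `units = "r"`).
#' @export
roi_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (any(!is.finite(ts))) stop_fc("time series contains non-finite values")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop_fc("zero-variance ROI column(s): %s", paste(bad, collapse = ", "))
  }
  m <- stats::cor(ts)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(m, class = c("connectivity_matrix", "matrix"), units = "r")
}

#' Define an ROI-to-network partition
#'
#' @param roi_labels Character vector of ROI labels.
#' @param networks Character vector (same length) of network labels; must be
#'   drawn from [canonical_networks()] unless `network_order` is supplied.
#' @param network_order Ordering of network labels used for block sorting;
#'   defaults to the canonical seven networks plus `"no_overlap"`.
#' @return A `network_partition` object.
#' @export
network_partition <- function(roi_labels, networks,
                              network_order = canonical_networks()) {
  if (length(roi_labels) != length(networks)) {
    stop_fc("roi_labels and networks must have equal length")
  }
  if (anyDuplicated(roi_labels)) stop_fc("duplicate ROI labels")
  unknown <- setdiff(networks, network_order)
  if (length(unknown)) {
    stop_fc("network label(s) not in network_order: %s",
            paste(unknown, collapse = ", "))
  }
  structure(list(roi_labels = roi_labels,
                 networks = stats::setNames(networks, roi_labels),
                 network_order = network_order),
            class = "network_partition")
}

#' Read a partition from a two-column TSV (roi_label, network)
#' @param path TSV path.
#' @inheritParams network_partition
#' @return A `network_partition`.
#' @export
read_partition_tsv <- function(path, network_order = canonical_networks()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  network_partition(df[[1L]], df[[2L]], network_order = network_order)
}

## Canonical edge ordering for a partition: edges grouped by unordered network
## pair (blocks ordered by canonical network indices, row-major), then by
## ascending (row, col) ROI index within block. Pure function of the
## partition + ROI label order, so identical across scans.
edge_order <- function(partition, roi_labels = partition$roi_labels) {
  nets <- partition$networks[roi_labels]
  if (any(is.na(nets))) {
    stop_fc("partition does not cover ROI(s): %s",
            paste(roi_labels[is.na(nets)], collapse = ", "))
  }
  ni <- match(nets, partition$network_order)
  R <- length(roi_labels)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)  # col-major i<j
  a <- pairs[, 1L]; b <- pairs[, 2L]
  bi <- pmin(ni[a], ni[b]); bj <- pmax(ni[a], ni[b])
  block <- paste(partition$network_order[bi], partition$network_order[bj],
                 sep = "--")
  ord <- order(bi, bj, a, b)
  ## canonical (alphabetical) label orientation so shuffled ROI input yields
  ## the same edge-label set
  l1 <- roi_labels[a[ord]]; l2 <- roi_labels[b[ord]]
  flip <- l2 < l1
  lab <- paste(ifelse(flip, l2, l1), ifelse(flip, l1, l2), sep = "--")
  data.frame(row = a[ord], col = b[ord],
             edge_label = lab,
             block = block[ord],
             within = (bi == bj)[ord],
             stringsAsFactors = FALSE)
}

#' Vectorize a connectivity matrix into a network-sorted edge vector
#'
#' Extracts the strict upper triangle, ordered first by unordered
#' network-pair block (blocks follow the canonical network order) and within
#' block by ascending ROI index pair, optionally applying the Fisher-z
#' transform `atanh(r)`.
#'
#' @param cm R x R connectivity matrix (r units) with ROI labels as dimnames,
#'   or a plain symmetric matrix.
#' @param partition A [network_partition()] covering all ROIs.
#' @param to_fisher_z Apply `atanh` to the values.
#' @param clip Clip `|r|` at `1 - 1e-7` before `atanh` rather than erroring
#'   on `|r| = 1`.
#' @return An `edge_vector`: list with `values`, `edge_labels`, `blocks`,
#'   `within` (logical, same-network edges), `units`, and the ordering table.
#' @export
vectorize_edges <- function(cm, partition, to_fisher_z = TRUE, clip = FALSE) {
  m <- unclass(cm)
  R <- nrow(m)
  roi_labels <- rownames(m) %||% partition$roi_labels
  if (length(roi_labels) != R) stop_fc("ROI labels do not match matrix size")
  eo <- edge_order(partition, roi_labels)
  vals <- m[cbind(eo$row, eo$col)]
  units <- "r"
  if (to_fisher_z) {
    if (any(abs(vals) >= 1)) {
      if (!clip) {
        stop_fc("|r| = 1 at edge(s) %s; Fisher z undefined (set clip = TRUE to clip)",
                paste(eo$edge_label[abs(vals) >= 1], collapse = ", "))
      }
      vals <- pmin(pmax(vals, -(1 - 1e-7)), 1 - 1e-7)
    }
    vals <- atanh(vals)
    units <- "fisher_z"
  }
  structure(list(values = stats::setNames(vals, eo$edge_label),
                 edge_labels = eo$edge_label,
                 blocks = eo$block,
                 within = eo$within,
                 units = units,
                 order = eo),
            class = "edge_vector")
}

#' Reassemble an edge vector into a symmetric matrix
#'
#' Inverse of [vectorize_edges()] for r-units vectors (unit diagonal).
#'
#' @param ev An `edge_vector`.
#' @param roi_labels ROI labels defining the matrix dimension.
#' @return Symmetric R x R matrix.
#' @export
edges_to_matrix <- function(ev, roi_labels) {
  R <- length(roi_labels)
  m <- diag(R)
  dimnames(m) <- list(roi_labels, roi_labels)
  vals <- ev$values
  if (ev$units == "fisher_z") vals <- tanh(vals)
  m[cbind(ev$order$row, ev$order$col)] <- vals
  m[cbind(ev$order$col, ev$order$row)] <- vals
  m
}

#' Compute an edge observation panel from a time-series panel
#'
#' Runs [roi_connectivity()] and [vectorize_edges()] on every scan of a
#' [simulate_timeseries_panel()] result (or any list of scans with `data`,
#' `subject`, `condition`, `session` entries) and assembles the edge vectors
#' into an [edge_panel()].
#'
#' @param tsp A `timeseries_panel` or compatible scan list.
#' @param partition A [network_partition()]; defaults to a single-network
#'   partition over the scans' ROIs.
#' @param to_fisher_z Store edges in Fisher-z units (default) or raw r.
#' @param nuisance Optional function applied to each scan's data matrix
#'   before correlation (e.g. a [nuisance_regress()] wrapper).
#' @return An `edge_panel` with `edge_blocks` set from the partition.
#' @export
connectivity_panel <- function(tsp, partition = NULL, to_fisher_z = TRUE,
                               nuisance = NULL) {
  stopifnot(length(tsp) > 0L)
  roi_labels <- colnames(tsp[[1L]]$data)
  if (is.null(partition)) {
    partition <- network_partition(roi_labels,
                                   rep("default", length(roi_labels)))
  }
  subjects <- unique(vapply(tsp, `[[`, character(1), "subject"))
  conditions <- unique(vapply(tsp, `[[`, character(1), "condition"))
  sessions <- sort(unique(vapply(tsp, function(s) as.integer(s$session),
                                 integer(1))))
  eo <- edge_order(partition, roi_labels)
  V <- nrow(eo)
  d <- c(length(subjects), length(conditions), length(sessions), V)
  values <- array(NA_real_, d,
                  dimnames = list(subjects, conditions,
                                  sprintf("ses-%02d", sessions),
                                  eo$edge_label))
  missing <- array(TRUE, d, dimnames = dimnames(values))
  for (scan in tsp) {
    x <- scan$data
    if (!is.null(nuisance)) x <- nuisance(x)
    ev <- vectorize_edges(roi_connectivity(x), partition,
                          to_fisher_z = to_fisher_z)
    k <- match(scan$subject, subjects)
    j <- match(scan$condition, conditions)
    i <- match(as.integer(scan$session), sessions)
    values[k, j, i, ] <- ev$values
    missing[k, j, i, ] <- FALSE
  }
  edge_panel(values, missing,
             units = if (to_fisher_z) "fisher_z" else "r",
             edge_blocks = eo$block)
}
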