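#' Construct an edge observation panel
#'
#' The unit of reliability analysis: edge-level connectivity values indexed by
#' (subject, condition, session, edge), together with a missingness mask and
#' a units flag. Values are stored even where masked; masked cells are simply
#' excluded by the estimators.
#'
#' @param values Numeric 4-d array, dimensions (subject, condition, session,
#'   edge). Dimnames, if absent, are generated.
#' @param missing Logical array of the same shape (default all `FALSE`).
#' @param units Either `"fisher_z"` or `"r"`. In `"r"` units all non-missing
#'   values must lie in `[-1, 1]`.
#' @param edge_blocks Optional character vector (length V) of network-block
#'   labels for the edges.
#' @return An `edge_panel` object.
#' @export
edge_panel <- function(values, missing = NULL, units = c("fisher_z", "r"),
                       edge_blocks = NULL) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop_fc("values must be a 4-d array (subject, condition, session, edge)")
  }
  d <- dim(values)
  if (is.null(missing)) {
    missing <- array(FALSE, d)
  }
  if (!is.logical(missing) || !identical(dim(missing), d)) {
    stop_fc("missing mask must be a logical array with the same shape as values")
  }
  dn <- dimnames(values)
  if (is.null(dn)) dn <- vector("list", 4L)
  defaults <- list(sprintf("sub-%02d", seq_len(d[1L])),
                   sprintf("cond%d", seq_len(d[2L])),
                   sprintf("ses-%02d", seq_len(d[3L])),
                   sprintf("edge%d", seq_len(d[4L])))
  for (k in 1:4) if (is.null(dn[[k]])) dn[[k]] <- defaults[[k]]
  names(dn) <- c("subject", "condition", "session", "edge")
  dimnames(values) <- dn
  dimnames(missing) <- dn
  if (units == "r") {
    obs <- values[!missing]
    if (any(!is.na(obs) & abs(obs) > 1)) {
      stop_fc("r-units panel contains values outside [-1, 1]")
    }
  }
  if (!is.null(edge_blocks) && length(edge_blocks) != d[4L]) {
    stop_fc("edge_blocks must have one label per edge")
  }
  structure(list(values = values, missing = missing, units = units,
                 edge_blocks = edge_blocks),
            class = "edge_panel")
}

#' @export
print.edge_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("edge_panel: %d subjects x %d conditions x %d sessions x %d edges (%s units), %d masked cells\n",
              d[1L], d[2L], d[3L], d[4L], x$units,
              sum(x$missing) / max(1L, d[4L])))
  invisible(x)
}

#' @export
dim.edge_panel <- function(x) dim(x$values)

#' Mark scan cells of a panel as missing
#'
#' Sets the missing mask at the named (subject, condition, session) cells for
#' all edges; values are preserved but flagged. A cell that would remove a
#' subject entirely is rejected when the panel has a single condition.
#'
#' @param panel An `edge_panel`.
#' @param cells Data frame (or matrix) with columns/cols `subject`,
#'   `condition`, `session` holding 1-based indices.
#' @return The panel with an updated mask.
#' @export
inject_missing <- function(panel, cells) {
  stopifnot(inherits(panel, "edge_panel"))
  if (is.null(cells) || NROW(cells) == 0L) return(panel)
  cells <- as.data.frame(cells)
  need <- c("subject", "condition", "session")
  if (!all(need %in% names(cells))) {
    names(cells)[1:3] <- need
  }
  d <- dim(panel$values)
  for (nm in need) cells[[nm]] <- as.integer(cells[[nm]])
  bounds <- c(subject = d[1L], condition = d[2L], session = d[3L])
  for (nm in need) {
    if (any(cells[[nm]] < 1L | cells[[nm]] > bounds[[nm]])) {
      stop_fc("cell index out of bounds in column '%s'", nm)
    }
  }
  mask <- panel$missing
  for (r in seq_len(nrow(cells))) {
    mask[cells$subject[r], cells$condition[r], cells$session[r], ] <- TRUE
  }
  ## a subject must retain at least one observed cell unless J > 1
  if (d[2L] == 1L) {
    for (k in unique(cells$subject)) {
      if (all(mask[k, , , 1L])) {
        stop_fc("masking would remove subject %d entirely (single-condition panel)", k)
      }
    }
  }
  panel$missing <- mask
  panel
}

#' Flatten a panel to scan-level edge vectors
#'
#' Each fully observed (subject, condition, session) cell becomes one row; the
#' scan metadata is returned alongside. Masked scans are dropped.
#'
#' @param panel An `edge_panel`.
#' @return List with `vectors` (S x V matrix) and `meta` (data.frame with
#'   subject, condition, session).
#' @export
panel_scans <- function(panel) {
  stopifnot(inherits(panel, "edge_panel"))
  d <- dim(panel$values)
  dn <- dimnames(panel$values)
  rows <- list(); meta <- list()
  for (k in seq_len(d[1L])) for (j in seq_len(d[2L])) for (i in seq_len(d[3L])) {
    if (any(panel$missing[k, j, i, ])) next
    rows[[length(rows) + 1L]] <- panel$values[k, j, i, ]
    meta[[length(meta) + 1L]] <- data.frame(
      subject = dn[[1L]][k], condition = dn[[2L]][j], session = dn[[3L]][i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_fc("panel has no fully observed scans")
  vectors <- do.call(rbind, rows)
  colnames(vectors) <- dn[[4L]]
  list(vectors = vectors, meta = do.call(rbind, meta))
}

#' Serialize / read an edge panel as long-format TSV
#'
#' Columns: subject, condition, session, edge, value, missing. A JSON sidecar
#' with the units flag and dimensions is written next to the TSV.
#'
#' @param panel An `edge_panel`.
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @return `write_edge_panel_tsv` returns `path` invisibly;
#'   `read_edge_panel_tsv` the reconstructed `edge_panel`.
#' @export
write_edge_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "edge_panel"))
  d <- dim(panel$values)
  dn <- dimnames(panel$values)
  idx <- expand.grid(subject = dn[[1L]], condition = dn[[2L]],
                     session = dn[[3L]], edge = dn[[4L]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(idx, value = as.vector(panel$values),
                   missing = as.vector(panel$missing))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(units = panel$units, dim = d, dimnames = dn,
                  edge_blocks = panel$edge_blocks)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_edge_panel_tsv
#' @export
read_edge_panel_tsv <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop_fc("missing sidecar %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  d <- as.integer(sc$dim)
  dn <- sc$dimnames
  values <- array(NA_real_, d, dimnames = dn)
  missing <- array(TRUE, d, dimnames = dn)
  ki <- match(df$subject, dn[[1L]])
  ji <- match(df$condition, dn[[2L]])
  ii <- match(df$session, dn[[3L]])
  vi <- match(df$edge, dn[[4L]])
  values[cbind(ki, ji, ii, vi)] <- df$value
  missing[cbind(ki, ji, ii, vi)] <- df$missing
  edge_blocks <- sc$edge_blocks
  if (!length(edge_blocks)) edge_blocks <- NULL
  edge_panel(values, missing, units = sc$units, edge_blocks = edge_blocks)
}
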