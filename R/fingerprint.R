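#' Scan-by-scan similarity matrix
#'
#' Pearson correlation between whole-connectome edge vectors, one per scan.
#'
#' @param edge_vectors S x V numeric matrix (rows = scans) or a list of
#'   [vectorize_edges()] results with identical edge order.
#' @return S x S symmetric correlation matrix with unit diagonal.
#' @export
similarity_matrix <- function(edge_vectors) {
  if (is.list(edge_vectors) && !is.matrix(edge_vectors)) {
    labs <- edge_vectors[[1L]]$edge_labels
    for (ev in edge_vectors) {
      if (!identical(ev$edge_labels, labs)) {
        stop_fc("edge vectors must share length and edge order")
      }
    }
    edge_vectors <- do.call(rbind, lapply(edge_vectors, function(ev) ev$values))
  }
  x <- as.matrix(edge_vectors)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0] %||% which(sds == 0)
    stop_fc("constant edge vector for scan(s): %s", paste(bad, collapse = ", "))
  }
  m <- stats::cor(t(x))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Within- versus between-subject similarity statistics
#'
#' Partitions all unordered scan pairs into same-subject and
#' different-subject sets and summarizes each: mean, SD, and
#' normal-approximation 95% confidence interval of the mean
#' (mean +/- 1.96 SD / sqrt(n_pairs)).
#'
#' @param similarity S x S similarity matrix.
#' @param subjects Character/factor vector of length S: subject of each scan.
#' @param meta Optional per-scan data.frame with `condition` and `session`
#'   columns; required for the restricted strata.
#' @param stratum `"all"` pools every same-subject pair regardless of
#'   condition and session; `"same_condition"` / `"same_session"` restrict
#'   the pairs (both sets) to pairs matching on that variable.
#' @return A `fingerprint_result` list: `similarity`, `scan_meta`,
#'   `within_stats`, `between_stats` (each mean, sd, ci_low, ci_high,
#'   n_pairs), and `pairs` (long data.frame of all pairs with class labels).
#' @export
within_between_stats <- function(similarity, subjects, meta = NULL,
                                 stratum = c("all", "same_condition",
                                             "same_session")) {
  stratum <- match.arg(stratum)
  S <- nrow(similarity)
  if (length(subjects) != S) stop_fc("need one subject label per scan")
  if (sum(table(subjects) >= 2L) < 1L || length(unique(subjects)) < 2L) {
    stop_fc("need >= 2 subjects and >= 2 scans for at least one subject")
  }
  idx <- which(upper.tri(similarity), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(idx))
  if (stratum != "all") {
    if (is.null(meta)) stop_fc("meta required for stratum '%s'", stratum)
    key <- if (stratum == "same_condition") meta$condition else meta$session
    keep <- key[idx[, 1L]] == key[idx[, 2L]]
  }
  idx <- idx[keep, , drop = FALSE]
  same <- subjects[idx[, 1L]] == subjects[idx[, 2L]]
  r <- similarity[idx]
  pairs <- data.frame(scan_a = idx[, 1L], scan_b = idx[, 2L], r = r,
                      pair_class = ifelse(same, "within", "between"),
                      stringsAsFactors = FALSE)
  summ <- function(v) {
    n <- length(v)
    if (n == 0L) stop_fc("empty pair set; cannot summarize")
    m <- mean(v); s <- stats::sd(v)
    half <- 1.96 * s / sqrt(n)
    list(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n_pairs = n)
  }
  structure(list(similarity = similarity,
                 scan_meta = if (is.null(meta)) {
                   data.frame(subject = subjects, stringsAsFactors = FALSE)
                 } else cbind(data.frame(subject = subjects), meta),
                 within_stats = summ(r[same]),
                 between_stats = summ(r[!same]),
                 pairs = pairs,
                 stratum = stratum),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  f <- function(st, lab) {
    cat(sprintf("  %s: mean %.3f, SD %.3f, 95%% CI %.3f-%.3f (n_pairs = %d)\n",
                lab, st$mean, st$sd, st$ci_low, st$ci_high, st$n_pairs))
  }
  cat(sprintf("Connectome fingerprint similarity (%d scans, stratum: %s)\n",
              nrow(x$similarity), x$stratum))
  f(x$within_stats, "same subject")
  f(x$between_stats, "different subject")
  invisible(x)
}

#' Nearest-neighbour subject identification accuracy
#'
#' For each scan, the predicted subject is the subject of the most similar
#' other scan; ties are broken by the lowest scan index. Accuracy is the
#' fraction of scans whose predicted subject matches their own.
#'
#' @param similarity S x S similarity matrix.
#' @param subjects Subject label per scan; every subject needs >= 2 scans.
#' @return Numeric accuracy in `[0, 1]`, with the per-scan predictions as
#'   attribute `"predicted"`.
#' @export
identify_subjects <- function(similarity, subjects) {
  S <- nrow(similarity)
  if (length(subjects) != S) stop_fc("need one subject label per scan")
  if (any(table(subjects) < 2L)) {
    stop_fc("every subject needs at least 2 scans for identification")
  }
  pred <- character(S)
  for (s in seq_len(S)) {
    sims <- similarity[s, ]
    sims[s] <- -Inf
    pred[s] <- subjects[which.max(sims)]  # which.max: lowest index on ties
  }
  structure(mean(pred == subjects), predicted = pred)
}
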