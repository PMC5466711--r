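#' Generate a counter-balanced session schedule
#'
#' Builds a schedule assigning each scan condition to one slot per session so
#' that, across the study, (1) every session contains each condition exactly
#' once, (2) each condition occupies each slot equally often, (3) each
#' condition is preceded within-session by each other condition equally often,
#' and (4) for every non-rest condition the stimulus exemplars rotate so that
#' each exemplar occurs exactly once in every consecutive block of
#' `n_exemplars` sessions. The default geometry (12 sessions, 4 conditions,
#' 3 exemplars) gives slot counts of 3 and predecessor counts of 3.
#'
#' The search uses randomized backtracking over session rows with count
#' propagation (slot and predecessor tallies capped at their exact balanced
#' values) and a bounded restart budget, so the result is deterministic given
#' `seed` while distinct seeds can yield distinct valid schedules.
#'
#' @param n_sessions Number of sessions; must be divisible by the number of
#'   conditions and by `n_exemplars`.
#' @param conditions Ordered character vector of condition labels. The label
#'   `"rest"` (if present) is treated as having a single fixed exemplar.
#' @param n_exemplars Number of stimulus exemplars per non-rest condition.
#' @param seed Integer seed controlling the randomized search.
#' @param subject_id Identifier stored in the schedule.
#' @param subject_index 1-based subject number; offsets the exemplar-ordering
#'   stream so different subjects receive different exemplar rotations from
#'   the same root seed.
#' @param max_restarts Restart budget before declaring the parameters
#'   infeasible.
#'
#' @return A `study_schedule` object: a list with the condition grid
#'   (`n_sessions` x `n_slots` character matrix), the exemplar grid (integer
#'   matrix of the same shape), and the design parameters.
#' @seealso [verify_schedule()], [write_schedule_tsv()]
#' @export
#' @examples
#' sch <- generate_schedule(seed = 1)
#' verify_schedule(sch)$pass
generate_schedule <- function(n_sessions = 12L,
                              conditions = c("rest", "inscapes", "movie", "flanker"),
                              n_exemplars = 3L,
                              seed = 1L,
                              subject_id = "sub-01",
                              subject_index = 1L,
                              max_restarts = 10000L) {
  n_sessions <- as.integer(n_sessions)
  n_exemplars <- as.integer(n_exemplars)
  n_slots <- length(conditions)
  if (n_slots < 2L) stop_fc("need at least 2 conditions")
  if (anyDuplicated(conditions)) stop_fc("condition labels must be unique")
  if (n_sessions %% n_slots != 0L) {
    stop_fc("n_sessions (%d) must be divisible by the number of conditions (%d)",
            n_sessions, n_slots)
  }
  if (n_sessions %% n_exemplars != 0L) {
    stop_fc("n_sessions (%d) must be divisible by n_exemplars (%d)",
            n_sessions, n_exemplars)
  }

  slot_cap <- n_sessions %/% n_slots      # appearances of each condition per slot
  pred_cap <- n_sessions %/% n_slots      # times each condition precedes each other

  grid <- with_local_seed(seed, {
    .search_condition_grid(n_sessions, conditions, slot_cap, pred_cap, max_restarts)
  })
  if (is.null(grid)) {
    stop_fc(paste0("no schedule satisfying slot-balance (cap %d) and ",
                   "predecessor-balance (cap %d) constraints found within %d restarts"),
            slot_cap, pred_cap, max_restarts)
  }

  ## Exemplar rotation: independent latin rotation per non-rest condition,
  ## one permutation of 1..n_exemplars per consecutive block of sessions.
  ## The stream is offset per subject so orderings differ across participants.
  exemplar_grid <- with_local_seed(derive_seed(seed, subject_index, 7919L), {
    eg <- matrix(1L, nrow = n_sessions, ncol = n_slots,
                 dimnames = dimnames(grid))
    n_blocks <- n_sessions %/% n_exemplars
    for (cond in setdiff(conditions, "rest")) {
      for (b in seq_len(n_blocks)) {
        rows <- ((b - 1L) * n_exemplars + 1L):(b * n_exemplars)
        perm <- sample.int(n_exemplars)
        for (r in seq_along(rows)) {
          eg[rows[r], grid[rows[r], ] == cond] <- perm[r]
        }
      }
    }
    eg
  })

  structure(
    list(subject_id = subject_id,
         condition_grid = grid,
         exemplar_grid = exemplar_grid,
         conditions = conditions,
         n_sessions = n_sessions,
         n_slots = n_slots,
         n_exemplars = n_exemplars),
    class = "study_schedule"
  )
}

## Randomized backtracking over session rows. Each row is a permutation of the
## conditions; partial assignments are pruned against the slot and predecessor
## caps. Returns the grid or NULL if the restart budget is exhausted.
.search_condition_grid <- function(n_sessions, conditions, slot_cap, pred_cap,
                                   max_restarts) {
  n_slots <- length(conditions)
  perms <- .permutations(n_slots)         # each row one permutation of indices

  for (restart in seq_len(max_restarts)) {
    slot_count <- matrix(0L, n_slots, n_slots)  # condition x slot
    pred_count <- matrix(0L, n_slots, n_slots)  # predecessor x successor
    rows <- vector("list", n_sessions)
    order_per_depth <- vector("list", n_sessions)
    choice_ptr <- integer(n_sessions)
    depth <- 1L
    order_per_depth[[1L]] <- sample.int(nrow(perms))
    choice_ptr[1L] <- 0L
    nodes <- 0L
    repeat {
      nodes <- nodes + 1L
      if (nodes > 50000L) break  # give up this restart, reshuffle
      choice_ptr[depth] <- choice_ptr[depth] + 1L
      if (choice_ptr[depth] > nrow(perms)) {
        ## exhausted choices at this depth: backtrack
        depth <- depth - 1L
        if (depth == 0L) break
        p <- perms[order_per_depth[[depth]][choice_ptr[depth]], ]
        for (s in seq_len(n_slots)) {
          slot_count[p[s], s] <- slot_count[p[s], s] - 1L
        }
        for (s in seq_len(n_slots - 1L)) {
          pred_count[p[s], p[s + 1L]] <- pred_count[p[s], p[s + 1L]] - 1L
        }
        next
      }
      p <- perms[order_per_depth[[depth]][choice_ptr[depth]], ]
      ok <- TRUE
      for (s in seq_len(n_slots)) {
        if (slot_count[p[s], s] + 1L > slot_cap) { ok <- FALSE; break }
      }
      if (ok) {
        for (s in seq_len(n_slots - 1L)) {
          if (pred_count[p[s], p[s + 1L]] + 1L > pred_cap) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      ## commit
      for (s in seq_len(n_slots)) {
        slot_count[p[s], s] <- slot_count[p[s], s] + 1L
      }
      for (s in seq_len(n_slots - 1L)) {
        pred_count[p[s], p[s + 1L]] <- pred_count[p[s], p[s + 1L]] + 1L
      }
      rows[[depth]] <- p
      if (depth == n_sessions) {
        grid <- matrix(conditions[do.call(rbind, rows)], n_sessions, n_slots)
        dimnames(grid) <- list(session = paste0("ses-", seq_len(n_sessions)),
                               slot = paste0("slot-", seq_len(n_slots)))
        return(grid)
      }
      depth <- depth + 1L
      order_per_depth[[depth]] <- sample.int(nrow(perms))
      choice_ptr[depth] <- 0L
    }
  }
  NULL
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Verify a schedule against the counter-balancing constraints
#'
#' Recounts every design constraint on a fully populated schedule and reports
#' observed tallies with pass/fail per constraint: session completeness (each
#' condition once per session), slot balance, predecessor balance, and
#' exemplar rotation per block of sessions.
#'
#' @param schedule A `study_schedule` object.
#' @return A `schedule_report` list: `pass` (logical), `constraints`
#'   (data.frame of constraint, observed, expected, pass), plus the raw
#'   `slot_counts` and `predecessor_counts` matrices and a character vector of
#'   `violations`.
#' @export
verify_schedule <- function(schedule) {
  if (!inherits(schedule, "study_schedule")) stop_fc("not a study_schedule")
  grid <- schedule$condition_grid
  conds <- schedule$conditions
  n_sessions <- schedule$n_sessions
  n_slots <- schedule$n_slots
  if (any(is.na(grid)) || !all(grid %in% conds)) {
    stop_fc("malformed grid: missing cell or unknown condition label")
  }
  if (!identical(dim(grid), c(n_sessions, n_slots))) {
    stop_fc("malformed grid: dimensions disagree with schedule metadata")
  }
  violations <- character(0)

  ## 1. each session contains each condition exactly once
  row_ok <- apply(grid, 1L, function(r) setequal(r, conds) && !anyDuplicated(r))
  if (!all(row_ok)) {
    violations <- c(violations, sprintf(
      "session(s) %s do not contain each condition exactly once",
      paste(which(!row_ok), collapse = ", ")))
  }

  ## 2. slot balance
  slot_cap <- n_sessions %/% n_slots
  slot_counts <- matrix(0L, length(conds), n_slots,
                        dimnames = list(condition = conds,
                                        slot = paste0("slot-", seq_len(n_slots))))
  for (s in seq_len(n_slots)) {
    tab <- table(factor(grid[, s], levels = conds))
    slot_counts[, s] <- as.integer(tab)
  }
  if (!all(slot_counts == slot_cap)) {
    bad <- which(slot_counts != slot_cap, arr.ind = TRUE)
    violations <- c(violations, sprintf(
      "slot balance violated for %s",
      paste(sprintf("(%s, slot %d): %d != %d", conds[bad[, 1L]], bad[, 2L],
                    slot_counts[bad], slot_cap), collapse = "; ")))
  }

  ## 3. predecessor balance (within-session transitions)
  pred_cap <- n_sessions %/% n_slots
  pred_counts <- matrix(0L, length(conds), length(conds),
                        dimnames = list(predecessor = conds, successor = conds))
  for (i in seq_len(n_sessions)) {
    for (s in seq_len(n_slots - 1L)) {
      a <- grid[i, s]; b <- grid[i, s + 1L]
      pred_counts[a, b] <- pred_counts[a, b] + 1L
    }
  }
  off <- pred_counts[row(pred_counts) != col(pred_counts)]
  if (!all(off == pred_cap)) {
    violations <- c(violations,
                    sprintf("predecessor balance violated: off-diagonal counts %s (expected all %d)",
                            paste(sort(unique(off)), collapse = "/"), pred_cap))
  }

  ## 4. exemplar rotation per block (non-rest conditions)
  eg <- schedule$exemplar_grid
  n_ex <- schedule$n_exemplars
  n_blocks <- n_sessions %/% n_ex
  for (cond in setdiff(conds, "rest")) {
    for (b in seq_len(n_blocks)) {
      rows <- ((b - 1L) * n_ex + 1L):(b * n_ex)
      ex <- vapply(rows, function(r) eg[r, grid[r, ] == cond], integer(1))
      if (!setequal(ex, seq_len(n_ex))) {
        violations <- c(violations, sprintf(
          "exemplar rotation violated for condition '%s' in session block %d (sessions %d-%d): saw {%s}",
          cond, b, rows[1L], rows[n_ex], paste(ex, collapse = ",")))
      }
    }
  }

  constraints <- data.frame(
    constraint = c("session_completeness", "slot_balance",
                   "predecessor_balance", "exemplar_rotation"),
    expected = c("each condition once per session",
                 sprintf("all counts = %d", slot_cap),
                 sprintf("all off-diagonal counts = %d", pred_cap),
                 sprintf("each exemplar once per %d-session block", n_ex)),
    pass = c(all(row_ok),
             all(slot_counts == slot_cap),
             all(off == pred_cap),
             !any(grepl("exemplar rotation", violations))),
    stringsAsFactors = FALSE
  )

  structure(list(pass = length(violations) == 0L,
                 constraints = constraints,
                 slot_counts = slot_counts,
                 predecessor_counts = pred_counts,
                 violations = violations),
            class = "schedule_report")
}

#' @export
print.schedule_report <- function(x, ...) {
  cat("Schedule constraint report:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$constraints, row.names = FALSE)
  if (length(x$violations)) {
    cat("Violations:\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}

#' @export
print.study_schedule <- function(x, ...) {
  cat(sprintf("study_schedule: %s, %d sessions x %d slots, conditions: %s\n",
              x$subject_id, x$n_sessions, x$n_slots,
              paste(x$conditions, collapse = ", ")))
  shown <- matrix(paste0(x$condition_grid, "[", x$exemplar_grid, "]"),
                  x$n_sessions, x$n_slots, dimnames = dimnames(x$condition_grid))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Write/read a schedule as tab-separated values
#'
#' Long format with columns `subject_id`, `session`, `slot`, `condition`,
#' `exemplar` (1-based indices).
#'
#' @param schedule A `study_schedule`.
#' @param path Output file path.
#' @return `write_schedule_tsv` returns `path` invisibly; `read_schedule_tsv`
#'   returns a `study_schedule`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  grid <- schedule$condition_grid
  df <- data.frame(
    subject_id = schedule$subject_id,
    session = rep(seq_len(schedule$n_sessions), each = schedule$n_slots),
    slot = rep(seq_len(schedule$n_slots), times = schedule$n_sessions),
    condition = as.vector(t(grid)),
    exemplar = as.vector(t(schedule$exemplar_grid)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @param conditions Condition ordering to impose; defaults to first-seen
#'   order in the file.
#' @param n_exemplars Exemplars per non-rest condition.
#' @export
read_schedule_tsv <- function(path, conditions = NULL, n_exemplars = 3L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "slot", "condition", "exemplar")
  if (!all(need %in% names(df))) {
    stop_fc("schedule TSV must have columns: %s", paste(need, collapse = ", "))
  }
  conditions <- conditions %||% unique(df$condition[order(df$session, df$slot)])
  n_sessions <- max(df$session)
  n_slots <- max(df$slot)
  grid <- matrix(NA_character_, n_sessions, n_slots,
                 dimnames = list(session = paste0("ses-", seq_len(n_sessions)),
                                 slot = paste0("slot-", seq_len(n_slots))))
  eg <- matrix(NA_integer_, n_sessions, n_slots, dimnames = dimnames(grid))
  grid[cbind(df$session, df$slot)] <- df$condition
  eg[cbind(df$session, df$slot)] <- df$exemplar
  structure(
    list(subject_id = df$subject_id[1L],
         condition_grid = grid,
         exemplar_grid = eg,
         conditions = conditions,
         n_sessions = n_sessions,
         n_slots = n_slots,
         n_exemplars = as.integer(n_exemplars)),
    class = "study_schedule"
  )
}
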