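## Classed errors so the command-line wrapper can map failures to distinct
## exit codes: config schema violations vs missing upstream artifacts vs
## stage failures.
stop_config <- function(fmt, ...) {
  stop(structure(class = c("fc_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}
stop_missing_input <- function(fmt, ...) {
  stop(structure(class = c("fc_missing_input", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file parsed into one) with:
#' `seed` (integer), `stages` (subset of simulate, connectivity, fingerprint,
#' reliability, duration, report), `sim` (arguments for [sim_config()]),
#' optional `flags` (`fisher_z`, `icc_include_residual`, `i2c2_block_mode`,
#' `anova_unit`), optional `duration` (`minutes` vector, `n_pseudosessions`),
#' and optional `partition` (path to a partition TSV).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated, normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_missing_input("config file not found: %s", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a named list or YAML path")
  known_stages <- c("simulate", "connectivity", "fingerprint", "reliability",
                    "duration", "report")
  config$stages <- config$stages %||%
    c("simulate", "connectivity", "fingerprint", "reliability", "report")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad)) stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.null(config$seed)) stop_config("config must set a seed")
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop_config("seed must be a single integer")
  }
  config$sim <- config$sim %||% list()
  if (!is.list(config$sim)) stop_config("sim block must be a list")
  flags <- config$flags %||% list()
  flags$fisher_z <- flags$fisher_z %||% TRUE
  flags$icc_include_residual <- flags$icc_include_residual %||% FALSE
  flags$i2c2_block_mode <- flags$i2c2_block_mode %||% "incident"
  flags$anova_unit <- flags$anova_unit %||% "scan"
  if (!flags$i2c2_block_mode %in% c("incident", "within")) {
    stop_config("i2c2_block_mode must be 'incident' or 'within'")
  }
  if (!flags$anova_unit %in% c("scan", "subject_mean")) {
    stop_config("anova_unit must be 'scan' or 'subject_mean'")
  }
  config$flags <- flags
  if ("duration" %in% config$stages) {
    config$duration <- config$duration %||% list()
    config$duration$minutes <- config$duration$minutes %||% c(10, 20, 30)
    config$duration$n_pseudosessions <- config$duration$n_pseudosessions %||% 4L
    if (is.null(config$sim$n_rois)) {
      stop_config("duration stage requires sim$n_rois (time-series simulation)")
    }
  }
  if (!is.null(config$partition) && !file.exists(config$partition)) {
    stop_missing_input("partition file not found: %s", config$partition)
  }
  config
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_sidecar <- function(path, stage, config_hash, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = config_hash, seed = seed,
         package = "fcreliab",
         version = as.character(utils::packageVersion("fcreliab"))),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the end-to-end reliability pipeline
#'
#' Executes the configured stages in dependency order — simulation,
#' connectivity/panel assembly, fingerprinting, reliability estimation,
#' scan-duration analysis, report — writing TSV/JSON artifacts (each with a
#' `.meta.json` sidecar carrying the config hash and seed) into `out_dir`.
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config Run configuration (list or YAML path); see
#'   [validate_run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .config_hash(config)
  seed <- as.integer(config$seed)
  res <- list(config = config, config_hash = hash)
  emit <- function(path, stage) .write_sidecar(path, stage, hash, seed)

  scfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
  ts_mode <- !is.null(scfg$n_rois)

  if ("simulate" %in% config$stages) {
    if (ts_mode) {
      res$tsp <- simulate_timeseries_panel(scfg)
    }
    res$sim <- simulate_edge_panel(scfg)
    p <- file.path(out_dir, "edge_panel.tsv")
    write_edge_panel_tsv(res$sim$panel, p); emit(p, "simulate")
  }

  partition <- NULL
  if (!is.null(config$partition)) partition <- read_partition_tsv(config$partition)

  if ("connectivity" %in% config$stages && ts_mode) {
    if (is.null(res$tsp)) stop_missing_input("connectivity stage needs the simulate stage's time series")
    res$panel <- connectivity_panel(res$tsp, partition = partition,
                                    to_fisher_z = config$flags$fisher_z)
    p <- file.path(out_dir, "connectivity_panel.tsv")
    write_edge_panel_tsv(res$panel, p); emit(p, "connectivity")
  }
  panel <- res$panel %||% res$sim$panel
  if (is.null(panel)) stop_missing_input("no panel available; include the simulate stage or supply one")

  if ("fingerprint" %in% config$stages) {
    sc <- panel_scans(panel)
    sim_m <- similarity_matrix(sc$vectors)
    res$fingerprint <- within_between_stats(sim_m, sc$meta$subject,
                                            meta = sc$meta)
    res$fingerprint$id_accuracy <- as.numeric(identify_subjects(sim_m, sc$meta$subject))
    p <- file.path(out_dir, "similarity.tsv")
    utils::write.table(round(sim_m, 10), p, sep = "\t", quote = FALSE)
    emit(p, "fingerprint")
    stats_out <- list(
      within = res$fingerprint$within_stats,
      between = res$fingerprint$between_stats,
      id_accuracy = res$fingerprint$id_accuracy)
    pj <- file.path(out_dir, "fingerprint_stats.json")
    jsonlite::write_json(stats_out, pj, auto_unbox = TRUE, digits = NA)
    emit(pj, "fingerprint")
    pp <- file.path(out_dir, "fingerprint_pairs.tsv")
    utils::write.table(res$fingerprint$pairs, pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(pp, "fingerprint")
  }

  if ("reliability" %in% config$stages) {
    fit <- fit_panel(panel,
                     include_residual_bc = config$flags$icc_include_residual)
    res$fit <- fit
    i2 <- if (!is.null(panel$edge_blocks)) {
      i2c2_by_network(panel, block_mode = config$flags$i2c2_block_mode)
    } else NULL
    res$summary <- summarize_reliability(fit, i2c2_values = i2)
    p <- file.path(out_dir, "per_edge_reliability.tsv")
    utils::write.table(fit, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p, "reliability")
    pj <- file.path(out_dir, "reliability_summary.json")
    jsonlite::write_json(list(percentiles = res$summary$percentiles,
                              network_cells = res$summary$network_cells,
                              i2c2 = as.list(i2 %||% list())),
                         pj, auto_unbox = TRUE, digits = NA)
    emit(pj, "reliability")
  }

  if ("duration" %in% config$stages) {
    if (is.null(res$tsp)) stop_missing_input("duration stage needs the simulate stage's time series")
    rows <- list()
    for (mins in config$duration$minutes) {
      dpanel <- duration_pseudosessions(
        res$tsp, minutes = mins,
        n_pseudosessions = config$duration$n_pseudosessions,
        seed = derive_seed(seed, round(mins)), partition = partition,
        to_fisher_z = config$flags$fisher_z)
      conds <- dimnames(dpanel$values)[[2L]]
      V <- dim(dpanel$values)[4L]
      for (cond in conds) {
        iccs <- vapply(seq_len(V), function(v) {
          as.numeric(per_condition_icc(dpanel, cond, v))
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, minutes = mins,
          median_icc = stats::median(iccs, na.rm = TRUE),
          mean_icc = mean(iccs, na.rm = TRUE), n_edges = V,
          stringsAsFactors = FALSE)
      }
    }
    res$duration <- do.call(rbind, rows)
    p <- file.path(out_dir, "duration_icc.tsv")
    utils::write.table(res$duration, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(p, "duration")
  }

  run_info <- list(config = config, config_hash = hash, seed = seed,
                   stages = config$stages,
                   version = as.character(utils::packageVersion("fcreliab")))
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  if ("report" %in% config$stages) {
    res$report <- pipeline_report(out_dir)
    writeLines(res$report, file.path(out_dir, "report.md"))
  }
  invisible(res)
}

#' Render a human-readable report from pipeline artifacts
#'
#' Reads the artifacts written by [run_pipeline()] and formats a deterministic
#' markdown report: fingerprint similarity statistics, ICC percentile lines,
#' within/between-network summary cells, network I2C2 values, and
#' per-duration median ICCs. Sections whose artifacts are absent are marked
#' as such; out-of-range ICC records abort with the offending record named.
#'
#' @param out_dir Directory holding the pipeline artifacts.
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(out_dir) {
  if (!dir.exists(out_dir)) stop_missing_input("artifact directory not found: %s", out_dir)
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  lines <- c("# Serial-scan reliability report", "")

  fp <- file.path(out_dir, "fingerprint_stats.json")
  lines <- c(lines, "## Connectome fingerprinting", "")
  if (file.exists(fp)) {
    st <- jsonlite::read_json(fp, simplifyVector = TRUE)
    lines <- c(lines,
      sprintf("- Same-subject similarity: mean %s, SD %s, 95%% CI %s-%s (n_pairs = %d)",
              fmt(st$within$mean), fmt(st$within$sd), fmt(st$within$ci_low),
              fmt(st$within$ci_high), st$within$n_pairs),
      sprintf("- Different-subject similarity: mean %s, SD %s, 95%% CI %s-%s (n_pairs = %d)",
              fmt(st$between$mean), fmt(st$between$sd), fmt(st$between$ci_low),
              fmt(st$between$ci_high), st$between$n_pairs),
      sprintf("- Identification accuracy: %s", fmt(st$id_accuracy)), "")
  } else {
    lines <- c(lines, "- (absent)", "")
  }

  rs <- file.path(out_dir, "reliability_summary.json")
  lines <- c(lines, "## Connection-wise reliability", "")
  if (file.exists(rs)) {
    su <- jsonlite::read_json(rs, simplifyVector = TRUE)
    pc <- su$percentiles
    bad_bc <- !is.na(pc$icc_between_condition) &
      (pc$icc_between_condition < 0 | pc$icc_between_condition > 1)
    bad_bs <- !is.na(pc$icc_between_session) &
      (pc$icc_between_session < 0 | pc$icc_between_session > 1)
    if (any(bad_bc) || any(bad_bs)) {
      stop_fc("reliability summary contains out-of-range ICC at percentile(s): %s",
              paste(pc$percentile[bad_bc | bad_bs], collapse = ", "))
    }
    lines <- c(lines,
      sprintf("- Between-condition ICC percentiles: 50th: %s, 75th: %s, 95th: %s",
              fmt(pc$icc_between_condition[1L]), fmt(pc$icc_between_condition[2L]),
              fmt(pc$icc_between_condition[3L])),
      sprintf("- Between-session ICC percentiles: 50th: %s, 75th: %s, 95th: %s",
              fmt(pc$icc_between_session[1L]), fmt(pc$icc_between_session[2L]),
              fmt(pc$icc_between_session[3L])), "")
    if (!is.null(su$network_cells) && length(su$network_cells)) {
      nc <- su$network_cells
      lines <- c(lines, "| ICC | scope | mean | SD | 95% CI | n edges |",
                 "|---|---|---|---|---|---|")
      for (r in seq_len(nrow(nc))) {
        lines <- c(lines, sprintf("| %s | %s | %s | %s | %s-%s | %d |",
                                  nc$icc[r], nc$scope[r], fmt(nc$mean[r]),
                                  fmt(nc$sd[r]), fmt(nc$ci_low[r]),
                                  fmt(nc$ci_high[r]), nc$n_edges[r]))
      }
      lines <- c(lines, "")
    }
    if (!is.null(su$i2c2) && length(su$i2c2)) {
      lines <- c(lines, "## Network-level I2C2", "")
      for (nm in names(su$i2c2)) {
        val <- su$i2c2[[nm]]
        if (!is.null(val) && !is.na(val) && (val < 0 || val > 1)) {
          stop_fc("out-of-range I2C2 for network '%s'", nm)
        }
        lines <- c(lines, sprintf("- %s: %s", nm,
                                  if (is.null(val) || is.na(val)) "NA" else fmt(val)))
      }
      lines <- c(lines, "")
    }
  } else {
    lines <- c(lines, "- (absent)", "")
  }

  du <- file.path(out_dir, "duration_icc.tsv")
  lines <- c(lines, "## Scan-duration analysis", "")
  if (file.exists(du)) {
    dd <- utils::read.table(du, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    lines <- c(lines, "| condition | minutes | median ICC | mean ICC |",
               "|---|---|---|---|")
    for (r in seq_len(nrow(dd))) {
      lines <- c(lines, sprintf("| %s | %g | %s | %s |", dd$condition[r],
                                dd$minutes[r], fmt(dd$median_icc[r]),
                                fmt(dd$mean_icc[r])))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "- (absent)", "")
  }
  lines
}
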