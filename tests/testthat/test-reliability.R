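test_that("mean squares match a brute-force sums-of-squares oracle exactly", {
  y <- array(c(1, 5, 2, 7, 4, 2, 9, 3), c(2, 2, 2))  # K=2, J=2, I=2 integers
  panel <- make_panel(y)
  got <- anova_moments(panel, 1)
  oracle <- brute_force_ms(y)
  expect_equal(got$ms_subject, oracle$ms_subject, tolerance = 1e-12)
  expect_equal(got$ms_cell, oracle$ms_cell, tolerance = 1e-12)
  expect_equal(got$ms_error, oracle$ms_error, tolerance = 1e-12)
  expect_equal(got$vc$sigma0_sq, oracle$ms_error, tolerance = 1e-12)
  expect_equal(got$vc$sigma2_sq, max(0, (oracle$ms_cell - oracle$ms_error) / 2),
               tolerance = 1e-12)
  expect_equal(got$vc$sigma3_sq,
               max(0, (oracle$ms_subject - oracle$ms_cell) / 4),
               tolerance = 1e-12)
  expect_equal(got$vc$mu, mean(y), tolerance = 1e-12)
})

test_that("constant panels give zero variance components", {
  y <- array(0.7, c(3, 2, 4))
  got <- anova_moments(make_panel(y), 1)
  expect_equal(got$vc$sigma3_sq, 0)
  expect_equal(got$vc$sigma2_sq, 0)
  expect_equal(got$vc$sigma0_sq, 0)
  expect_equal(got$vc$mu, 0.7)
})

test_that("single-condition panels use the reduced two-level formulas", {
  set.seed(10)
  y <- array(rnorm(5 * 1 * 6), c(5, 1, 6))
  got <- anova_moments(make_panel(y), 1)
  expect_true(is.na(got$vc$sigma2_sq))
  ym <- y[, 1, ]
  expect_equal(got$vc$sigma0_sq,
               sum((ym - rowMeans(ym))^2) / (5 * (6 - 1)), tolerance = 1e-12)
})

test_that("vectorized panel MoM agrees with the per-edge path", {
  cfg <- study_sim_config(n_edges = 30, seed = 20)
  panel <- simulate_edge_panel(cfg)$panel
  tab <- fcreliab:::fit_panel_mom(panel)
  for (v in c(1, 13, 30)) {
    vc <- anova_moments(panel, v)$vc
    expect_equal(tab$sigma3_sq[v], vc$sigma3_sq, tolerance = 1e-12)
    expect_equal(tab$sigma2_sq[v], vc$sigma2_sq, tolerance = 1e-12)
    expect_equal(tab$sigma0_sq[v], vc$sigma0_sq, tolerance = 1e-12)
  }
})

test_that("REML agrees with MoM on complete balanced panels with interior estimates", {
  cfg <- study_sim_config(n_edges = 25, seed = 30)
  panel <- simulate_edge_panel(cfg)$panel
  checked <- 0
  for (v in 1:25) {
    mom <- anova_moments(panel, v)$vc
    if (min(mom$sigma3_sq, mom$sigma2_sq, mom$sigma0_sq) <= 1e-3) next
    reml <- fit_em_reml(panel, v)
    expect_true(reml$converged)
    expect_equal(reml$sigma3_sq, mom$sigma3_sq, tolerance = 1e-6)
    expect_equal(reml$sigma2_sq, mom$sigma2_sq, tolerance = 1e-6)
    expect_equal(reml$sigma0_sq, mom$sigma0_sq, tolerance = 1e-6)
    expect_equal(reml$mu, mom$mu, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 15)
})

test_that("REML matches lme4 on an incomplete panel", {
  skip_if_not_installed("lme4")
  cfg <- study_sim_config(n_edges = 3, seed = 31,
                          missingness = flanker_missingness())
  panel <- simulate_edge_panel(cfg)$panel
  for (v in 1:3) {
    got <- fit_em_reml(panel, v)
    y <- as.vector(panel$values[, , , v])
    miss <- as.vector(panel$missing[, , , v])
    idx <- expand.grid(subject = 1:10, condition = 1:4, session = 1:12)
    df <- data.frame(y = y, subject = factor(idx$subject),
                     cell = factor(paste(idx$subject, idx$condition)))[!miss, ]
    fit <- lme4::lmer(y ~ 1 + (1 | subject) + (1 | cell), data = df,
                      REML = TRUE)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    s3_l <- vcs$vcov[vcs$grp == "subject"]
    s2_l <- vcs$vcov[vcs$grp == "cell"]
    s0_l <- vcs$vcov[vcs$grp == "Residual"]
    expect_equal(got$sigma3_sq, s3_l, tolerance = 1e-3)
    expect_equal(got$sigma2_sq, s2_l, tolerance = 1e-3)
    expect_equal(got$sigma0_sq, s0_l, tolerance = 1e-4)
  }
})

test_that("REML recovers the truth under the flanker missingness pattern", {
  cfg <- study_sim_config(n_edges = 150, seed = 32,
                          missingness = flanker_missingness())
  panel <- simulate_edge_panel(cfg)$panel
  tab <- fit_panel(panel, estimator = "reml")
  expect_true(all(tab$converged))
  expect_equal(mean(tab$sigma3_sq), 0.04, tolerance = 0.15)
  expect_equal(mean(tab$sigma2_sq), 0.01, tolerance = 0.15)
  expect_equal(mean(tab$sigma0_sq), 0.10, tolerance = 0.05)
})

test_that("boundary truths drive the REML variance estimates to zero", {
  cfg <- sim_config(n_subjects = 10, n_conditions = 4, n_sessions = 12,
                    n_edges = 60, mu = 0, sigma3_sq = 0, sigma2_sq = 0,
                    sigma0_sq = 0.1, seed = 33)
  panel <- simulate_edge_panel(cfg)$panel
  panel <- inject_missing(panel, flanker_missingness())
  tab <- fit_panel(panel, estimator = "reml")
  expect_lt(median(tab$sigma3_sq), 0.005)
  expect_lt(median(tab$sigma2_sq), 0.005)
})

test_that("non-identifiable missingness patterns raise informative errors", {
  vals <- array(rnorm(2 * 2 * 2 * 1), c(2, 2, 2, 1))
  panel <- edge_panel(vals)
  # every subject sees only one condition
  m <- panel$missing
  m[1, 2, , ] <- TRUE
  m[2, 1, , ] <- TRUE
  panel$missing <- m
  expect_error(fit_em_reml(panel, 1), "condition-level")
})

test_that("ICC formulas evaluate exactly on fixed component triples", {
  vc <- variance_components(0, 3, 1, 4)
  expect_equal(icc_between_condition(vc), 0.75)
  expect_equal(icc_between_session(vc), 0.5)
  expect_equal(icc_between_condition(variance_components(0, 2, 0, 1)), 1)
  expect_equal(icc_between_condition(variance_components(0, 0, 2, 1)), 0)
  expect_true(is.na(icc_between_condition(variance_components(0, 0, 0, 1))))
  expect_equal(icc_between_session(variance_components(0, 1, 2, 0)), 1)
  expect_true(is.na(icc_between_session(variance_components(0, 0, 0, 0))))
  expect_equal(icc_between_session(variance_components(0, 0.04, 0.01, 0.10)),
               1 / 3, tolerance = 1e-12)
  # total-variance-normalized alternative
  expect_equal(icc_between_condition(vc, include_residual = TRUE), 3 / 8)
  # negative moment estimates are clamped
  expect_equal(variance_components(0, -0.2, 1, 1)$sigma3_sq, 0)
  expect_true(variance_components(0, -0.2, 1, 1)$clamped[1])
})

test_that("per-condition ICC behaves at its extremes and matches the ANOVA oracle", {
  # sessions identical within subject, subjects differ -> 1
  y <- array(0, c(3, 1, 4))
  y[, 1, ] <- matrix(c(1, 2, 3), 3, 4)
  expect_equal(as.numeric(per_condition_icc(make_panel(y), 1, 1)), 1,
               tolerance = 1e-6)

  # equal subject means, pure within noise -> near zero
  set.seed(40)
  y2 <- array(rnorm(6 * 1 * 8), c(6, 1, 8))
  y2[, 1, ] <- y2[, 1, ] - rowMeans(y2[, 1, ])
  expect_lt(as.numeric(per_condition_icc(make_panel(y2), 1, 1)), 0.05)

  # balanced toy: REML within estimator-class tolerance of the one-way MoM
  set.seed(41)
  for (r in 1:5) {
    ym <- matrix(rnorm(3 * 4, sd = 0.3), 3, 4) + c(0, 0.5, 1.2)
    y3 <- array(ym, c(3, 1, 4))
    got <- as.numeric(per_condition_icc(make_panel(y3), 1, 1))
    expect_equal(got, oneway_icc_oracle(ym), tolerance = 0.02)
  }
})

test_that("per-condition ICC handles missing sessions and matches lme4", {
  skip_if_not_installed("lme4")
  set.seed(42)
  y <- array(rnorm(8 * 1 * 6, sd = 0.3) + rep(rnorm(8, sd = 0.5), 6),
             c(8, 1, 6))
  panel <- make_panel(y)
  panel$missing[2, 1, 5:6, ] <- TRUE
  got <- as.numeric(per_condition_icc(panel, 1, 1))
  df <- data.frame(y = as.vector(y[, 1, ]), subject = factor(rep(1:8, 6)),
                   obs = !as.vector(panel$missing[, 1, , 1]))
  fit <- lme4::lmer(y ~ 1 + (1 | subject), data = df[df$obs, ], REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fit))
  icc_l <- vcs$vcov[1] / sum(vcs$vcov)
  expect_equal(got, icc_l, tolerance = 1e-4)
})

test_that("univariate I2C2 equals the one-way trace quantity exactly", {
  set.seed(50)
  W <- matrix(rnorm(12), 12, 1)
  subs <- rep(letters[1:4], each = 3)
  got <- i2c2(W, subs)
  msw <- sum(unlist(lapply(split(W[, 1], subs),
                           function(v) (v - mean(v))^2))) / (12 - 4)
  mst <- var(W[, 1])
  expect_equal(got, max(0, min(1, 1 - msw / mst)), tolerance = 1e-12)
})

test_that("I2C2 is one for identical replicates and recovers the pooled ICC target", {
  W <- rbind(c(1, 2), c(1, 2), c(5, 6), c(5, 6))
  expect_equal(i2c2(W, c("a", "a", "b", "b")), 1)

  # replicates = sessions, grouped by subject-by-condition cell: the stable
  # part of a cell is delta + gamma, so the trace ratio targets
  # (s3 + s2) / (s3 + s2 + s0)
  cfg <- study_sim_config(n_edges = 1000, seed = 51)
  panel <- simulate_edge_panel(cfg)$panel
  sc <- panel_scans(panel)
  grp <- paste(sc$meta$subject, sc$meta$condition)
  lambda <- i2c2(sc$vectors, grp)
  target <- (0.04 + 0.01) / (0.04 + 0.01 + 0.10)
  expect_lt(abs(lambda - target), 0.05)
  expect_true(is.na(i2c2(matrix(1, 4, 2), c("a", "a", "b", "b"))))
})

test_that("network-level I2C2 respects the block mode and tracks edge-level ICC", {
  cfg <- sim_config(n_subjects = 8, n_conditions = 2, n_sessions = 6,
                    n_rois = 10, n_timepoints = 250, mu = 0.2,
                    sigma3_sq = 0.06, sigma2_sq = 0.01, sigma0_sq = 0.04,
                    seed = 52)
  tsp <- simulate_timeseries_panel(cfg)
  part <- network_partition(sprintf("roi%03d", 1:10),
                            rep(c("visual", "default"), each = 5))
  panel <- connectivity_panel(tsp, partition = part)
  vals <- i2c2_by_network(panel)
  expect_named(vals, c("visual", "default", "full"))
  expect_true(all(vals >= 0 & vals <= 1))
  within_only <- i2c2_by_network(panel, block_mode = "within")
  expect_true(all(within_only >= 0 & within_only <= 1, na.rm = TRUE))
  # incident blocks include more edges than within blocks
  expect_false(identical(vals[["visual"]], within_only[["visual"]]))
})

test_that("summaries compute interpolated percentiles and network cells", {
  fit <- data.frame(icc_bc = rep(0.5, 10), icc_bs = rep(0.5, 10))
  su <- summarize_reliability(fit, within = rep(c(TRUE, FALSE), 5))
  expect_true(all(su$percentiles$icc_between_session == 0.5))
  expect_true(all(su$network_cells$mean == 0.5))
  expect_true(all(su$network_cells$sd == 0))
  expect_true(all(su$network_cells$ci_low == su$network_cells$ci_high))

  fit2 <- data.frame(icc_bc = seq(0.1, 1.0, by = 0.1),
                     icc_bs = seq(0.1, 1.0, by = 0.1))
  su2 <- summarize_reliability(fit2)
  pcs <- su2$percentiles$icc_between_session
  expect_equal(pcs[su2$percentiles$percentile == "50th"], 0.55)
  expect_true(all(diff(pcs) >= 0))

  # boosted within-network subject variance shows up in the cell means
  set.seed(53)
  n <- 200
  within <- rep(c(TRUE, FALSE), each = n / 2)
  icc <- ifelse(within, rbeta(n, 8, 2), rbeta(n, 2, 8))
  fit3 <- data.frame(icc_bc = icc, icc_bs = icc)
  su3 <- summarize_reliability(fit3, within = within)
  cells <- su3$network_cells
  expect_gt(cells$mean[cells$icc == "icc_bs" & cells$scope == "within_network"],
            cells$mean[cells$icc == "icc_bs" & cells$scope == "between_network"])
})

test_that("scalar measure reliability separates traits from noise and detects shifts", {
  K <- 12; J <- 3; I <- 6
  set.seed(60)
  trait <- rnorm(K, 50, 10)
  vals <- array(NA_real_, c(K, J, I, 2),
                dimnames = list(NULL, c("rest", "movie", "flanker"), NULL,
                                c("snr", "fd")))
  # measure 1: pure subject trait (tiny session noise) -> ICC ~ 1
  vals[, , , 1] <- trait + rnorm(K * J * I, sd = 0.01)
  # measure 2: condition-shifted with large shift -> ANOVA p < 0.001
  shift <- c(0, 0, 5)
  vals[, , , 2] <- rep(shift, each = K) + rnorm(K * J * I, sd = 0.5)
  res <- scalar_measure_reliability(vals)
  icc_snr <- res$icc$icc[res$icc$measure == "snr"]
  expect_true(all(icc_snr > 0.99))
  expect_lt(res$anova$p[res$anova$measure == "fd"], 0.001)
  expect_gt(res$anova$p[res$anova$measure == "snr"], 0.05)
  expect_equal(res$anova$df1, c(J - 1, J - 1))

  # subject-mean ANOVA unit also flags the shift
  res2 <- scalar_measure_reliability(vals, anova_unit = "subject_mean")
  expect_lt(res2$anova$p[res2$anova$measure == "fd"], 0.001)

  # constant measure is flagged, not fitted
  vals[, , , 1] <- 1
  res3 <- scalar_measure_reliability(vals)
  expect_true(all(is.na(res3$icc$icc[res3$icc$measure == "snr"])))
})

test_that("pseudo-sessions partition the sessions disjointly and exactly", {
  cfg <- sim_config(n_subjects = 3, n_conditions = 2, n_sessions = 12,
                    n_rois = 6, n_timepoints = 80, seed = 70)
  tsp <- simulate_timeseries_panel(cfg)
  dp <- duration_pseudosessions(tsp, minutes = 30, seed = 5)
  expect_equal(dim(dp$values)[3], 4L)
  asg <- attr(dp, "assignments")
  for (sub in unique(asg$subject)) for (cond in unique(asg$condition)) {
    sel <- asg[asg$subject == sub & asg$condition == cond, ]
    expect_equal(nrow(sel), 12)                 # 4 pseudo-sessions x 3 sessions
    expect_setequal(sel$session, 1:12)          # covers all, hence disjoint
    expect_true(all(table(sel$pseudosession) == 3))
  }
  # determinism
  dp2 <- duration_pseudosessions(tsp, minutes = 30, seed = 5)
  expect_identical(dp$values, dp2$values)
  expect_error(duration_pseudosessions(tsp, minutes = 15, seed = 1),
               "multiple")
  expect_error(duration_pseudosessions(tsp[1:20], minutes = 30, seed = 1),
               "available")
})

test_that("base-duration pseudo-sessions are single sessions from the panel", {
  cfg <- sim_config(n_subjects = 2, n_conditions = 1, n_sessions = 5,
                    n_rois = 5, n_timepoints = 80, seed = 71)
  tsp <- simulate_timeseries_panel(cfg)
  dp <- duration_pseudosessions(tsp, minutes = 10, seed = 3)
  full <- connectivity_panel(tsp)
  asg <- attr(dp, "assignments")
  for (r in seq_len(nrow(asg))) {
    expect_equal(dp$values[asg$subject[r], 1, asg$pseudosession[r], ],
                 full$values[asg$subject[r], 1, asg$session[r], ],
                 tolerance = 1e-12)
  }
})
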