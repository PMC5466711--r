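# Shared fixture builders and independent oracles used across test files.

# Tiny balanced panel with prescribed values; y is a K x J x I array.
make_panel <- function(y, units = "fisher_z") {
  edge_panel(array(y, c(dim(y), 1L)), units = units)
}

# Independent brute-force nested sums of squares for one edge (explicit
# loops, no shared code with the implementation).
brute_force_ms <- function(y) {
  K <- dim(y)[1]; J <- dim(y)[2]; I <- dim(y)[3]
  gm <- sum(y) / (K * J * I)
  ss_sub <- 0
  for (k in 1:K) {
    yk <- 0
    for (j in 1:J) for (i in 1:I) yk <- yk + y[k, j, i]
    yk <- yk / (J * I)
    ss_sub <- ss_sub + (yk - gm)^2
  }
  ss_cell <- 0; ss_err <- 0
  for (k in 1:K) {
    yk <- mean(y[k, , ])
    for (j in 1:J) {
      yjk <- 0
      for (i in 1:I) yjk <- yjk + y[k, j, i]
      yjk <- yjk / I
      ss_cell <- ss_cell + (yjk - yk)^2
      for (i in 1:I) ss_err <- ss_err + (y[k, j, i] - yjk)^2
    }
  }
  list(ms_subject = J * I * ss_sub / (K - 1),
       ms_cell = I * ss_cell / (K * (J - 1)),
       ms_error = ss_err / (K * J * (I - 1)))
}

# Brute-force Pearson correlation from the textbook formula.
brute_force_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# One-way ANOVA method-of-moments ICC oracle for a balanced K x I layout.
oneway_icc_oracle <- function(y) {
  K <- nrow(y); I <- ncol(y)
  gm <- mean(y)
  msb <- I * sum((rowMeans(y) - gm)^2) / (K - 1)
  msw <- sum((y - rowMeans(y))^2) / (K * (I - 1))
  max(0, (msb - msw) / (msb + (I - 1) * msw))
}

# Standard study conditions used by the recovery and acceptance checks.
study_sim_config <- function(n_edges = 1000L, seed = 42L, missingness = NULL) {
  sim_config(n_subjects = 10L, n_conditions = 4L, n_sessions = 12L,
             n_edges = n_edges, mu = 0.3, sigma3_sq = 0.04, sigma2_sq = 0.01,
             sigma0_sq = 0.10, seed = seed, missingness = missingness)
}

# The observed missingness pattern emulated by the generator: three subjects
# each lack the flanker condition in one session.
flanker_missingness <- function() {
  data.frame(subject = 1:3, condition = 4L, session = c(2L, 5L, 9L))
}
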