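#' Variance components of the three-level connectivity model
#'
#' Container for per-edge estimates of the grand mean and the three variance
#' components: between subjects (`sigma3_sq`), between conditions within
#' subject (`sigma2_sq`), and between sessions / residual (`sigma0_sq`).
#'
#' @param mu Grand mean estimate.
#' @param sigma3_sq,sigma2_sq,sigma0_sq Variance component estimates;
#'   negative inputs are clamped to zero (clamping recorded in `clamped`).
#' @param estimator `"mom"` (balanced ANOVA method of moments) or `"reml"`.
#' @param converged Logical; `FALSE` flags the estimates as unusable.
#' @param n_used Number of observations used.
#' @return A `variance_components` object.
#' @export
variance_components <- function(mu, sigma3_sq, sigma2_sq, sigma0_sq,
                                estimator = c("mom", "reml"),
                                converged = TRUE, n_used = NA_integer_) {
  estimator <- match.arg(estimator)
  raw <- c(sigma3_sq, sigma2_sq, sigma0_sq)
  clamped <- !is.na(raw) & raw < 0
  structure(list(mu = mu,
                 sigma3_sq = max(0, sigma3_sq),
                 sigma2_sq = if (is.na(sigma2_sq)) NA_real_ else max(0, sigma2_sq),
                 sigma0_sq = max(0, sigma0_sq),
                 estimator = estimator, converged = converged,
                 n_used = as.integer(n_used),
                 clamped = clamped),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s%s): mu = %.4f, sigma3^2 = %.5f, sigma2^2 = %s, sigma0^2 = %.5f (n = %d)\n",
              x$estimator, if (x$converged) "" else ", NOT CONVERGED",
              x$mu, x$sigma3_sq,
              if (is.na(x$sigma2_sq)) "NA" else sprintf("%.5f", x$sigma2_sq),
              x$sigma0_sq, x$n_used))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Balanced ANOVA method of moments

#' Balanced-ANOVA mean squares and moment estimates for one edge
#'
#' For complete balanced data (no missing cells), computes the three-level
#' nested mean squares and the method-of-moments variance component
#' estimates. With grand mean \eqn{\bar y}, subject means \eqn{\bar y_k} and
#' subject-by-condition cell means \eqn{\bar y_{jk}}:
#' \deqn{MS_{subject} = J I \sum_k (\bar y_k - \bar y)^2 / (K - 1)}
#' \deqn{MS_{cell} = I \sum_{k,j} (\bar y_{jk} - \bar y_k)^2 / (K (J - 1))}
#' \deqn{MS_{error} = \sum (y - \bar y_{jk})^2 / (K J (I - 1))}
#' and \eqn{\hat\sigma_0^2 = MS_{error}},
#' \eqn{\hat\sigma_2^2 = (MS_{cell} - MS_{error}) / I},
#' \eqn{\hat\sigma_3^2 = (MS_{subject} - MS_{cell}) / (I J)}, each clamped at
#' zero. With a single condition the reduced two-level formulas are used and
#' `sigma2_sq` is `NA`.
#'
#' @param panel An [edge_panel()] with no missing cells at the edge.
#' @param edge Edge index or label.
#' @return List with `ms_subject`, `ms_cell`, `ms_error`, and `vc`
#'   (a [variance_components()] with `estimator = "mom"`).
#' @export
anova_moments <- function(panel, edge = 1L) {
  stopifnot(inherits(panel, "edge_panel"))
  v <- .edge_index(panel, edge)
  if (any(panel$missing[, , , v])) {
    stop_fc("edge '%s' has missing cells; use fit_em_reml()", edge)
  }
  y <- panel$values[, , , v, drop = FALSE]
  dim(y) <- dim(panel$values)[1:3]
  K <- dim(y)[1L]; J <- dim(y)[2L]; I <- dim(y)[3L]
  if (K < 2L || I < 2L) stop_fc("need K >= 2 subjects and I >= 2 sessions")
  gm <- mean(y)
  ybar_k <- apply(y, 1L, mean)
  if (J >= 2L) {
    ybar_jk <- apply(y, c(1L, 2L), mean)
    ms_subject <- J * I * sum((ybar_k - gm)^2) / (K - 1)
    ms_cell <- I * sum(sweep(ybar_jk, 1L, ybar_k)^2) / (K * (J - 1))
    ms_error <- sum(sweep(y, c(1L, 2L), ybar_jk)^2) / (K * J * (I - 1))
    s0 <- ms_error
    s2 <- (ms_cell - ms_error) / I
    s3 <- (ms_subject - ms_cell) / (I * J)
  } else {
    ms_subject <- I * sum((ybar_k - gm)^2) / (K - 1)
    ms_cell <- NA_real_
    ms_error <- sum(sweep(y, 1L, ybar_k)^2) / (K * (I - 1))
    s0 <- ms_error
    s2 <- NA_real_
    s3 <- (ms_subject - ms_error) / I
  }
  list(ms_subject = ms_subject, ms_cell = ms_cell, ms_error = ms_error,
       vc = variance_components(gm, s3, s2, s0, estimator = "mom",
                                n_used = K * J * I))
}

.edge_index <- function(panel, edge) {
  if (is.character(edge)) {
    v <- match(edge, dimnames(panel$values)[[4L]])
    if (is.na(v)) stop_fc("unknown edge label '%s'", edge)
    v
  } else {
    as.integer(edge)
  }
}

## Vectorized balanced MoM across all edges of a complete panel.
## Returns a data.frame, one row per edge.
fit_panel_mom <- function(panel) {
  stopifnot(inherits(panel, "edge_panel"))
  if (any(panel$missing)) stop_fc("panel has missing cells; use estimator 'reml'")
  y <- panel$values
  d <- dim(y); K <- d[1L]; J <- d[2L]; I <- d[3L]; V <- d[4L]
  gm <- apply(y, 4L, mean)
  ybar_k <- apply(y, c(1L, 4L), mean)
  if (J >= 2L) {
    ybar_jk <- apply(y, c(1L, 2L, 4L), mean)
    ms_subject <- J * I * colSums(sweep(ybar_k, 2L, gm)^2) / (K - 1)
    dev_cell <- sweep(ybar_jk, c(1L, 3L), ybar_k)
    ms_cell <- I * apply(dev_cell^2, 3L, sum) / (K * (J - 1))
    dev_err <- sweep(y, c(1L, 2L, 4L), ybar_jk)
    ms_error <- apply(dev_err^2, 4L, sum) / (K * J * (I - 1))
    s0 <- ms_error
    s2 <- pmax(0, (ms_cell - ms_error) / I)
    s3 <- pmax(0, (ms_subject - ms_cell) / (I * J))
  } else {
    ms_subject <- I * colSums(sweep(ybar_k, 2L, gm)^2) / (K - 1)
    dev_err <- sweep(y, c(1L, 4L), ybar_k)
    ms_error <- apply(dev_err^2, 4L, sum) / (K * (I - 1))
    s0 <- ms_error
    s2 <- rep(NA_real_, V)
    s3 <- pmax(0, (ms_subject - ms_error) / I)
  }
  data.frame(edge = dimnames(y)[[4L]], mu = gm,
             sigma3_sq = s3, sigma2_sq = s2, sigma0_sq = s0,
             estimator = "mom", converged = TRUE,
             n_used = K * J * I, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## REML for incomplete panels

## Precompute the missingness-pattern structure shared by all edges.
## For subject k with observed cells, the random-effect design is
## Z_k = [1 | condition indicators] (condition columns only when J > 1),
## and V_k = sigma0 I + Z_k D Z_k' with D = diag(sigma3, sigma2 I).
.reml_structure <- function(subject, condition, n_obs) {
  subs <- unique(subject)
  lapply(subs, function(s) {
    rows <- which(subject == s)
    conds <- condition[rows]
    uc <- unique(conds)
    with_cond <- length(uc) > 0L && !all(is.na(uc))
    if (with_cond) {
      Z <- cbind(1, stats::model.matrix(~ 0 + factor(conds, levels = uc)))
    } else {
      Z <- matrix(1, length(rows), 1L)
    }
    list(rows = rows, n = length(rows), q = ncol(Z),
         n_cond = if (with_cond) length(uc) else 0L,
         ZtZ = crossprod(Z), Zt1 = colSums(Z), Z = Z)
  })
}

## REML criterion value plus analytic score (gradient wrt the variances),
## both from the per-subject Woodbury blocks. The score is
##   d(-2l)/d theta_l = tr(P G_l) - y' P G_l P y,   G_l = dV/d theta_l,
## with P the REML projection; G_3 and G_2 are Z_l Z_l' for the subject and
## subject-by-condition designs, G_0 = I.
.reml_eval <- function(th, struct, y, two_level = FALSE) {
  if (two_level) {
    s3 <- th[1L]; s2 <- NA_real_; s0 <- th[2L]
  } else {
    s3 <- th[1L]; s2 <- th[2L]; s0 <- th[3L]
  }
  K <- length(struct)
  logdetV <- 0; A <- 0; B <- 0; Cq <- 0
  cache <- vector("list", K)
  for (ki in seq_len(K)) {
    st <- struct[[ki]]
    yk <- y[st$rows]
    d_inv <- if (st$n_cond > 0L) c(1 / s3, rep(1 / s2, st$n_cond)) else 1 / s3
    M <- s0 * diag(d_inv, st$q) + st$ZtZ
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(th)),
                                 mu = NA_real_))
    logdetM <- 2 * sum(log(diag(ch)))
    logdetD <- if (st$n_cond > 0L) log(s3) + st$n_cond * log(s2) else log(s3)
    logdetV <- logdetV + (st$n - st$q) * log(s0) + logdetD + logdetM
    u <- crossprod(st$Z, yk)
    w <- st$Zt1
    Minv_u <- backsolve(ch, forwardsolve(t(ch), u))
    Minv_w <- backsolve(ch, forwardsolve(t(ch), w))
    A <- A + (sum(yk^2) - sum(u * Minv_u)) / s0
    B <- B + (sum(yk) - sum(w * Minv_u)) / s0
    Cq <- Cq + (st$n - sum(w * Minv_w)) / s0
    cache[[ki]] <- list(ch = ch, u = u, w = w, Minv_w = Minv_w, yk = yk)
  }
  value <- logdetV + log(Cq) + (A - B^2 / Cq)
  if (!is.finite(value)) {
    return(list(value = 1e10, grad = rep(0, length(th)), mu = NA_real_))
  }
  mu <- B / Cq

  ## score accumulation
  tr3 <- 0; tr2 <- 0; tr0 <- 0          # tr(Z_l' V^-1 Z_l), tr(V^-1)
  c3 <- 0; c2 <- 0; c0 <- 0             # ||Z_l' V^-1 1||^2 terms
  q3 <- 0; q2 <- 0; q0 <- 0             # y' P G_l P y terms
  for (ki in seq_len(K)) {
    st <- struct[[ki]]; ca <- cache[[ki]]
    ch <- ca$ch
    ## Z'V^-1 Z = (ZtZ - ZtZ M^-1 ZtZ)/s0 ; Z'V^-1 1 = (w - ZtZ M^-1 w)/s0
    Minv_ZtZ <- backsolve(ch, forwardsolve(t(ch), st$ZtZ))
    Bk <- (st$ZtZ - st$ZtZ %*% Minv_ZtZ) / s0
    gk <- (ca$w - st$ZtZ %*% backsolve(ch, forwardsolve(t(ch), ca$w))) / s0
    r <- ca$u - mu * ca$w
    hk <- (r - st$ZtZ %*% backsolve(ch, forwardsolve(t(ch), r))) / s0
    tr3 <- tr3 + Bk[1L, 1L]
    c3 <- c3 + gk[1L]^2
    q3 <- q3 + hk[1L]^2
    if (st$n_cond > 0L) {
      ci <- 2L:st$q
      tr2 <- tr2 + sum(diag(Bk)[ci])
      c2 <- c2 + sum(gk[ci]^2)
      q2 <- q2 + sum(hk[ci]^2)
    }
    ## residual component: tr(V^-1), ||V^-1 1||^2, ||P y||^2
    Minv_r <- backsolve(ch, forwardsolve(t(ch), r))
    Minv_w <- ca$Minv_w
    tr0 <- tr0 + (st$n - sum(diag(Minv_ZtZ))) / s0
    c0 <- c0 + (st$n - 2 * sum(ca$w * Minv_w) +
                  sum(Minv_w * (st$ZtZ %*% Minv_w))) / s0^2
    ek2 <- sum(ca$yk^2) - 2 * mu * sum(ca$yk) + mu^2 * st$n
    q0 <- q0 + (ek2 - 2 * sum(r * Minv_r) +
                  sum(Minv_r * (st$ZtZ %*% Minv_r))) / s0^2
  }
  g3 <- (tr3 - c3 / Cq) - q3
  g0 <- (tr0 - c0 / Cq) - q0
  grad <- if (two_level) c(g3, g0) else c(g3, (tr2 - c2 / Cq) - q2, g0)
  list(value = value, grad = grad, mu = mu)
}

## Generic REML fit on long-format observations. `condition = NULL` gives the
## two-level subject/session model. Optimizes log-variances (L-BFGS-B), so
## nonnegativity holds by construction; boundary truths land near the lower
## bound and are clamped to zero below `zero_tol`.
.reml_fit <- function(y, subject, condition = NULL, start = NULL,
                      tol = 1e-8, maxit = 500L, zero_tol = 1e-7) {
  ok <- !is.na(y)
  y <- y[ok]; subject <- subject[ok]
  if (!is.null(condition)) condition <- condition[ok]
  n <- length(y)
  if (length(unique(subject)) < 2L) stop_fc("need >= 2 subjects with data")
  two_level <- is.null(condition) || length(unique(condition)) < 2L
  if (two_level) {
    if (!any(table(subject) >= 2L)) {
      stop_fc("within-subject variance not identifiable: no subject has >= 2 observations")
    }
    condition <- NULL
  } else {
    cell <- paste(subject, condition)
    if (!any(table(cell) >= 2L)) {
      stop_fc("session-level variance not identifiable: no subject-by-condition cell has >= 2 observations")
    }
  }
  struct <- .reml_structure(subject, condition %||% rep(NA_character_, n), n)
  if (two_level) for (i in seq_along(struct)) struct[[i]]$n_cond <- 0L

  vy <- stats::var(y)
  if (vy < 1e-12) {
    ## constant response: all components zero
    th <- if (two_level) c(0, 0) else c(0, 0, 0)
    return(list(mu = mean(y), theta = th, converged = TRUE, n_used = n,
                neg2ll = NA_real_))
  }
  if (is.null(start)) {
    start <- if (two_level) c(vy / 2, vy / 2) else rep(vy / 3, 3L)
  }
  start <- pmax(start, vy * 1e-3)
  np <- length(start)
  last <- new.env(parent = emptyenv())
  evalf <- function(lp) {
    key <- paste(lp, collapse = ",")
    if (!identical(last$key, key)) {
      last$res <- .reml_eval(exp(lp), struct, y, two_level)
      last$key <- key
    }
    last$res
  }
  opt <- stats::optim(log(start),
                      fn = function(lp) evalf(lp)$value,
                      gr = function(lp) evalf(lp)$grad * exp(lp),
                      method = "L-BFGS-B",
                      lower = rep(log(1e-9), np), upper = rep(log(1e4), np),
                      control = list(maxit = maxit, factr = 10, pgtol = 1e-10))
  th <- exp(opt$par)
  ## L-BFGS-B can stop with a line-search warning when already at the
  ## optimum; judge convergence by the scaled score instead of the code alone
  final <- .reml_eval(pmax(th, 1e-12), struct, y, two_level)
  score_ok <- max(abs(final$grad * th)) < 1e-4 * max(1, abs(final$value))
  converged <- opt$convergence == 0 || score_ok
  th[th < zero_tol * vy] <- 0
  list(mu = final$mu, theta = th, converged = converged, n_used = n,
       neg2ll = final$value)
}

#' REML estimation of the three-level variance components for one edge
#'
#' Restricted-maximum-likelihood fit of the Gaussian random-effects model
#' (subject, subject-by-condition, session-level residual) for a single edge,
#' valid with arbitrary missingness patterns. The REML criterion (with the
#' grand mean profiled out) is maximized over log-variances, so estimates are
#' nonnegative by construction; on complete balanced data with interior
#' estimates the result agrees with [anova_moments()].
#'
#' @param panel An [edge_panel()].
#' @param edge Edge index or label.
#' @param tol Convergence tolerance passed to the optimizer.
#' @param maxit Maximum iterations.
#' @return A [variance_components()] with `estimator = "reml"`.
#' @export
fit_em_reml <- function(panel, edge = 1L, tol = 1e-8, maxit = 500L) {
  stopifnot(inherits(panel, "edge_panel"))
  v <- .edge_index(panel, edge)
  d <- dim(panel$values)
  y <- as.vector(panel$values[, , , v])
  miss <- as.vector(panel$missing[, , , v])
  idx <- expand.grid(subject = seq_len(d[1L]), condition = seq_len(d[2L]),
                     session = seq_len(d[3L]), KEEP.OUT.ATTRS = FALSE)
  y[miss] <- NA
  ok <- !is.na(y)
  sub <- idx$subject[ok]; cond <- idx$condition[ok]; yy <- y[ok]
  if (length(unique(sub)) < 2L) stop_fc("need >= 2 subjects with observed data")
  if (d[2L] > 1L && max(tapply(cond, sub, function(x) length(unique(x)))) < 2L) {
    stop_fc("condition-level variance not identifiable: no subject observed under >= 2 conditions")
  }
  ## MoM warm start from crude nested moments on the observed data
  start <- NULL
  if (d[2L] > 1L) {
    cell_means <- tapply(yy, list(sub, cond), mean)
    sub_means <- tapply(yy, sub, mean)
    s0_0 <- stats::var(yy - cell_means[cbind(as.character(sub), as.character(cond))])
    s3_0 <- stats::var(sub_means)
    s2_0 <- stats::var(as.vector(cell_means), na.rm = TRUE) - s3_0
    start <- pmax(c(s3_0, s2_0, s0_0), 1e-4)
  }
  fit <- .reml_fit(yy, sub, if (d[2L] > 1L) cond else NULL,
                   start = start, tol = tol, maxit = maxit)
  if (length(fit$theta) == 2L) {
    variance_components(fit$mu, fit$theta[1L], NA_real_, fit$theta[2L],
                        estimator = "reml", converged = fit$converged,
                        n_used = fit$n_used)
  } else {
    variance_components(fit$mu, fit$theta[1L], fit$theta[2L], fit$theta[3L],
                        estimator = "reml", converged = fit$converged,
                        n_used = fit$n_used)
  }
}

#' Fit variance components for every edge of a panel
#'
#' Dispatches between the balanced ANOVA method of moments (complete panels)
#' and per-edge REML (any missingness). Returns a per-edge table with the
#' component estimates and both intraclass correlation coefficients.
#'
#' @param panel An [edge_panel()].
#' @param estimator `"auto"` (MoM when complete, REML otherwise), `"mom"`, or
#'   `"reml"`.
#' @param include_residual_bc Add the session-level residual to the
#'   between-condition ICC denominator (off by default; see
#'   [icc_between_condition()]).
#' @return data.frame with columns edge, block (if the panel carries edge
#'   blocks), mu, sigma3_sq, sigma2_sq, sigma0_sq, icc_bc, icc_bs, estimator,
#'   converged, n_used.
#' @export
fit_panel <- function(panel, estimator = c("auto", "mom", "reml"),
                      include_residual_bc = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(panel, "edge_panel"))
  has_missing <- any(panel$missing)
  if (estimator == "mom" && has_missing) {
    stop_fc("panel has missing cells; MoM requires complete data")
  }
  use_mom <- (estimator == "mom") || (estimator == "auto" && !has_missing)
  if (use_mom) {
    out <- fit_panel_mom(panel)
  } else {
    V <- dim(panel$values)[4L]
    rows <- vector("list", V)
    for (v in seq_len(V)) {
      vc <- fit_em_reml(panel, v)
      rows[[v]] <- data.frame(edge = dimnames(panel$values)[[4L]][v],
                              mu = vc$mu, sigma3_sq = vc$sigma3_sq,
                              sigma2_sq = vc$sigma2_sq,
                              sigma0_sq = vc$sigma0_sq,
                              estimator = "reml", converged = vc$converged,
                              n_used = vc$n_used, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  }
  out$icc_bc <- mapply(function(s3, s2, s0) {
    .icc_bc_value(s3, s2, s0, include_residual_bc)
  }, out$sigma3_sq, out$sigma2_sq, out$sigma0_sq)
  out$icc_bs <- mapply(.icc_bs_value, out$sigma3_sq,
                       ifelse(is.na(out$sigma2_sq), 0, out$sigma2_sq),
                       out$sigma0_sq)
  if (!is.null(panel$edge_blocks)) out$block <- panel$edge_blocks
  out
}

## ---------------------------------------------------------------------------
## Intraclass correlation coefficients

.icc_bc_value <- function(s3, s2, s0, include_residual = FALSE) {
  if (is.na(s2)) return(NA_real_)
  den <- s3 + s2 + if (include_residual) s0 else 0
  if (den <= 0) return(NA_real_)
  s3 / den
}

.icc_bs_value <- function(s3, s2, s0) {
  den <- s3 + s2 + s0
  if (den <= 0) return(NA_real_)
  (s3 + s2) / den
}

#' Between-condition intraclass correlation
#'
#' The ratio of between-subject variance to the sum of between-subject and
#' between-condition variance, \eqn{\sigma_3^2 / (\sigma_3^2 + \sigma_2^2)}:
#' the proportion of subject-plus-condition variability attributable to
#' stable subject differences. The session-level residual is deliberately
#' absent from the denominator; `include_residual = TRUE` gives the
#' total-variance-normalized alternative
#' \eqn{\sigma_3^2 / (\sigma_3^2 + \sigma_2^2 + \sigma_0^2)}.
#'
#' @param vc A [variance_components()] object.
#' @param include_residual Add \eqn{\sigma_0^2} to the denominator.
#' @return ICC in `[0, 1]`, or `NA` when the denominator is zero.
#' @export
icc_between_condition <- function(vc, include_residual = FALSE) {
  stopifnot(inherits(vc, "variance_components"))
  .icc_bc_value(vc$sigma3_sq, vc$sigma2_sq, vc$sigma0_sq, include_residual)
}

#' Between-session (test-retest) intraclass correlation
#'
#' \eqn{(\sigma_3^2 + \sigma_2^2) / (\sigma_3^2 + \sigma_2^2 + \sigma_0^2)}:
#' the proportion of total variance not attributable to session-to-session
#' noise.
#'
#' @param vc A [variance_components()] object.
#' @return ICC in `[0, 1]`, or `NA` when total variance is zero.
#' @export
icc_between_session <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  s2 <- if (is.na(vc$sigma2_sq)) 0 else vc$sigma2_sq
  .icc_bs_value(vc$sigma3_sq, s2, vc$sigma0_sq)
}

#' Per-condition connection-wise ICC (two-level mixed model)
#'
#' Restricting the panel to one condition, fits the two-level model
#' \eqn{y_{ik} = \mu + b_k + e_{ik}} with \eqn{b_k \sim N(0, \sigma_b^2)},
#' \eqn{e_{ik} \sim N(0, \sigma_w^2)} by REML across sessions, and returns
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}. Missing sessions are
#' handled by the likelihood.
#'
#' @param panel An [edge_panel()].
#' @param condition Condition label or index to restrict to.
#' @param edge Edge index or label.
#' @return ICC in `[0, 1]` (`NA` if total variance is zero), with the fitted
#'   components as attribute `"vc"`.
#' @export
per_condition_icc <- function(panel, condition, edge = 1L) {
  stopifnot(inherits(panel, "edge_panel"))
  j <- if (is.character(condition)) {
    match(condition, dimnames(panel$values)[[2L]])
  } else as.integer(condition)
  if (is.na(j) || j < 1L || j > dim(panel$values)[2L]) {
    stop_fc("unknown condition '%s'", condition)
  }
  v <- .edge_index(panel, edge)
  y <- panel$values[, j, , v]
  y[panel$missing[, j, , v]] <- NA
  K <- nrow(y)
  sub <- rep(seq_len(K), times = ncol(y))
  yy <- as.vector(y)
  ok <- !is.na(yy)
  fit <- .reml_fit(yy[ok], sub[ok])
  tot <- sum(fit$theta)
  icc <- if (tot <= 0) NA_real_ else fit$theta[1L] / tot
  attr(icc, "vc") <- variance_components(fit$mu, fit$theta[1L], NA_real_,
                                         fit$theta[2L], estimator = "reml",
                                         converged = fit$converged,
                                         n_used = fit$n_used)
  icc
}

## ---------------------------------------------------------------------------
## I2C2: multivariate (image-level) reliability

#' Image intraclass correlation (trace method-of-moments estimator)
#'
#' Multivariate analogue of the intraclass correlation for replicate
#' p-dimensional measurements \eqn{W_s} grouped by subject: with subject
#' means \eqn{\bar W_k} and grand mean \eqn{\bar W},
#' \deqn{\lambda = 1 - \frac{\sum_k \sum_{s \in k} \|W_s - \bar W_k\|^2 / \sum_k (n_k - 1)}
#'                        {\sum_s \|W_s - \bar W\|^2 / (S - 1)}}
#' clamped to `[0, 1]`. For p = 1 this is the univariate
#' `1 - MSW/MST` quantity.
#'
#' @param W S x p numeric matrix: one replicate observation per row.
#' @param subjects Subject label per row; >= 2 subjects, >= 2 replicates for
#'   at least one subject.
#' @return Scalar in `[0, 1]`, or `NA` when total variance is zero.
#' @export
i2c2 <- function(W, subjects) {
  W <- as.matrix(W)
  S <- nrow(W)
  if (length(subjects) != S) stop_fc("need one subject label per row")
  tab <- table(subjects)
  if (length(tab) < 2L || !any(tab >= 2L)) {
    stop_fc("need >= 2 subjects and >= 2 replicates for at least one subject")
  }
  gm <- colMeans(W)
  tr_total <- sum(sweep(W, 2L, gm)^2) / (S - 1)
  if (tr_total <= 0) return(NA_real_)
  ssw <- 0; dfw <- 0
  for (s in names(tab)) {
    if (tab[[s]] < 2L) next
    Wk <- W[subjects == s, , drop = FALSE]
    ssw <- ssw + sum(sweep(Wk, 2L, colMeans(Wk))^2)
    dfw <- dfw + nrow(Wk) - 1L
  }
  tr_within <- ssw / dfw
  min(1, max(0, 1 - tr_within / tr_total))
}

#' Network-level I2C2 from an edge panel
#'
#' Treats each fully observed scan of a subject as one replicate of the edge
#' vector and computes [i2c2()] per network block and for the full vector.
#' A network's block is, by default, every edge incident to it (edges whose
#' network pair involves the network); `block_mode = "within"` restricts to
#' edges with both ROIs in the network.
#'
#' @param panel An [edge_panel()] carrying `edge_blocks` labels of the form
#'   `"netA--netB"` (as produced by [connectivity_panel()]).
#' @param networks Networks to report; defaults to those present.
#' @param block_mode `"incident"` or `"within"`.
#' @return Named numeric vector of I2C2 values (one per network plus
#'   `"full"`).
#' @export
i2c2_by_network <- function(panel, networks = NULL,
                            block_mode = c("incident", "within")) {
  block_mode <- match.arg(block_mode)
  stopifnot(inherits(panel, "edge_panel"))
  if (is.null(panel$edge_blocks)) stop_fc("panel has no edge block labels")
  sc <- panel_scans(panel)
  parts <- strsplit(panel$edge_blocks, "--", fixed = TRUE)
  net_a <- vapply(parts, `[[`, character(1), 1L)
  net_b <- vapply(parts, `[[`, character(1), 2L)
  networks <- networks %||% unique(c(net_a, net_b))
  out <- vapply(networks, function(nw) {
    sel <- if (block_mode == "incident") {
      net_a == nw | net_b == nw
    } else {
      net_a == nw & net_b == nw
    }
    if (!any(sel)) return(NA_real_)
    i2c2(sc$vectors[, sel, drop = FALSE], sc$meta$subject)
  }, numeric(1))
  c(out, full = i2c2(sc$vectors, sc$meta$subject))
}

## ---------------------------------------------------------------------------
## Summaries

#' Summarize per-edge ICCs and network-level reliability
#'
#' Percentiles (50th, 75th, 95th; linear interpolation between order
#' statistics) of each ICC distribution, plus within-network versus
#' between-network cell summaries (mean, SD, normal-approximation 95% CI of
#' the mean).
#'
#' @param fit Per-edge data.frame from [fit_panel()] (columns `icc_bc`,
#'   `icc_bs`, optionally `block`).
#' @param within Optional logical vector marking within-network edges;
#'   derived from `fit$block` when absent.
#' @param i2c2_values Optional named vector from [i2c2_by_network()].
#' @param condition Label recorded in the summary (default `"all"`).
#' @return A `reliability_summary` list with `percentiles` (data.frame),
#'   `network_cells` (data.frame of icc x within/between cells), `i2c2`,
#'   and `condition`.
#' @export
summarize_reliability <- function(fit, within = NULL, i2c2_values = NULL,
                                  condition = "all") {
  if (is.null(within) && !is.null(fit$block)) {
    parts <- strsplit(fit$block, "--", fixed = TRUE)
    within <- vapply(parts, function(p) p[1L] == p[2L], logical(1))
  }
  probs <- c(0.5, 0.75, 0.95)
  pct <- function(x) stats::quantile(x, probs, na.rm = TRUE, type = 7, names = FALSE)
  percentiles <- data.frame(
    percentile = c("50th", "75th", "95th"),
    icc_between_condition = if (all(is.na(fit$icc_bc))) NA_real_ else pct(fit$icc_bc),
    icc_between_session = pct(fit$icc_bs)
  )
  cell <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) return(c(mean = NA, sd = NA, ci_low = NA, ci_high = NA, n = 0))
    m <- mean(x); s <- stats::sd(x)
    half <- 1.96 * s / sqrt(n)
    c(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
  }
  network_cells <- NULL
  if (!is.null(within)) {
    rows <- list()
    for (icc_name in c("icc_bc", "icc_bs")) {
      for (w in c(TRUE, FALSE)) {
        st <- cell(fit[[icc_name]][within == w])
        if (st[["n"]] == 0) {
          warning(sprintf("no edges in %s/%s cell; omitted", icc_name,
                          if (w) "within" else "between"), call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          icc = icc_name, scope = if (w) "within_network" else "between_network",
          mean = st[["mean"]], sd = st[["sd"]], ci_low = st[["ci_low"]],
          ci_high = st[["ci_high"]], n_edges = st[["n"]],
          stringsAsFactors = FALSE)
      }
    }
    network_cells <- do.call(rbind, rows)
  }
  structure(list(percentiles = percentiles, network_cells = network_cells,
                 i2c2 = i2c2_values, condition = condition,
                 n_edges = nrow(fit)),
            class = "reliability_summary")
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat(sprintf("Reliability summary (condition: %s, %d edges)\n", x$condition,
              x$n_edges))
  cat("Percentiles:\n")
  print(format(x$percentiles, digits = 3), row.names = FALSE)
  if (!is.null(x$network_cells)) {
    cat("Within/between network cells:\n")
    print(format(x$network_cells, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$i2c2)) {
    cat("I2C2 by network:\n")
    print(round(x$i2c2, 3))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Scalar quality measures

#' Reliability and condition effects of scalar per-scan measures
#'
#' For each (measure, condition) pair, the test-retest ICC from the two-level
#' subject/session model (as in [per_condition_icc()]); for each measure, a
#' one-way ANOVA F-test of condition on scan-level values pooled over
#' subjects and sessions (`anova_unit = "subject_mean"` averages sessions
#' within subject x condition first).
#'
#' @param values 4-d numeric array (subject, condition, session, measure);
#'   `NA` entries are treated as missing scans.
#' @param anova_unit `"scan"` (default) or `"subject_mean"`.
#' @return List with `icc` (data.frame measure, condition, icc, converged)
#'   and `anova` (data.frame measure, F, df1, df2, p).
#' @export
scalar_measure_reliability <- function(values,
                                       anova_unit = c("scan", "subject_mean")) {
  anova_unit <- match.arg(anova_unit)
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop_fc("values must be a 4-d array (subject, condition, session, measure)")
  }
  d <- dim(values)
  dn <- dimnames(values) %||% list(NULL, NULL, NULL, NULL)
  measures <- dn[[4L]] %||% sprintf("measure%d", seq_len(d[4L]))
  conditions <- dn[[2L]] %||% sprintf("cond%d", seq_len(d[2L]))
  icc_rows <- list(); anova_rows <- list()
  for (m in seq_len(d[4L])) {
    for (j in seq_len(d[2L])) {
      y <- values[, j, , m]
      if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
        icc_rows[[length(icc_rows) + 1L]] <- data.frame(
          measure = measures[m], condition = conditions[j], icc = NA_real_,
          converged = FALSE, stringsAsFactors = FALSE)
        next
      }
      sub <- rep(seq_len(d[1L]), times = d[3L])
      yy <- as.vector(y); ok <- !is.na(yy)
      fit <- .reml_fit(yy[ok], sub[ok])
      tot <- sum(fit$theta)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        measure = measures[m], condition = conditions[j],
        icc = if (tot <= 0) NA_real_ else fit$theta[1L] / tot,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
    if (d[2L] >= 2L) {
      if (anova_unit == "scan") {
        yy <- as.vector(values[, , , m])
        cond <- factor(rep(rep(conditions, each = d[1L]), times = d[3L]),
                       levels = conditions)
      } else {
        sm <- apply(values[, , , m, drop = FALSE], c(1L, 2L), mean, na.rm = TRUE)
        yy <- as.vector(sm)
        cond <- factor(rep(conditions, each = d[1L]), levels = conditions)
      }
      ok <- !is.na(yy)
      fit <- stats::aov(yy[ok] ~ cond[ok])
      tab <- stats::anova(fit)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        measure = measures[m], F = tab$`F value`[1L],
        df1 = tab$Df[1L], df2 = tab$Df[2L], p = tab$`Pr(>F)`[1L],
        stringsAsFactors = FALSE)
    }
  }
  list(icc = do.call(rbind, icc_rows),
       anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL)
}

## ---------------------------------------------------------------------------
## Scan-duration pseudo-session analysis

#' Build pseudo-session edge panels at increasing scan durations
#'
#' Per subject and condition, sessions are sampled without replacement and
#' partitioned into `n_pseudosessions` disjoint groups of
#' `minutes / session_minutes` sessions; each group's time series are
#' concatenated temporally and run through [roi_connectivity()] and
#' [vectorize_edges()]. The result is an edge panel whose session index is
#' the pseudo-session index, keeping the number of replicates constant while
#' the amount of data per replicate grows.
#'
#' @param tsp A `timeseries_panel` (see [simulate_timeseries_panel()]).
#' @param minutes Pseudo-session duration; must be a multiple of
#'   `session_minutes`.
#' @param n_pseudosessions Number of pseudo-sessions (replicates) per
#'   subject x condition.
#' @param seed Seed for the session sampling.
#' @param partition Optional [network_partition()].
#' @param session_minutes Duration represented by one original session.
#' @param to_fisher_z Store edges in Fisher-z units.
#' @return An [edge_panel()].
#' @export
duration_pseudosessions <- function(tsp, minutes, n_pseudosessions = 4L,
                                    seed = 1L, partition = NULL,
                                    session_minutes = 10,
                                    to_fisher_z = TRUE) {
  stopifnot(length(tsp) > 0L)
  if (minutes %% session_minutes != 0) {
    stop_fc("minutes (%s) must be a multiple of session_minutes (%s)",
            minutes, session_minutes)
  }
  g <- as.integer(minutes / session_minutes)  # sessions per pseudo-session
  need <- n_pseudosessions * g
  assignments <- list()
  meta <- data.frame(
    subject = vapply(tsp, `[[`, character(1), "subject"),
    condition = vapply(tsp, `[[`, character(1), "condition"),
    session = vapply(tsp, function(s) as.integer(s$session), integer(1)),
    stringsAsFactors = FALSE)
  scans <- list()
  for (sub in unique(meta$subject)) {
    for (cond in unique(meta$condition)) {
      avail <- which(meta$subject == sub & meta$condition == cond)
      if (length(avail) < need) {
        stop_fc("subject %s, condition %s: %d sessions available, %d needed for %g-min pseudo-sessions",
                sub, cond, length(avail), need, minutes)
      }
      picked <- with_local_seed(derive_seed(seed,
                                            match(sub, unique(meta$subject)),
                                            match(cond, unique(meta$condition))), {
        sample(avail, need)
      })
      for (ps in seq_len(n_pseudosessions)) {
        grp <- picked[((ps - 1L) * g + 1L):(ps * g)]
        data <- do.call(rbind, lapply(tsp[grp], `[[`, "data"))
        scans[[length(scans) + 1L]] <- list(data = data, subject = sub,
                                            condition = cond, session = ps)
        assignments[[length(assignments) + 1L]] <- data.frame(
          subject = sub, condition = cond, pseudosession = ps,
          session = meta$session[grp], stringsAsFactors = FALSE)
      }
    }
  }
  out <- connectivity_panel(scans, partition = partition,
                            to_fisher_z = to_fisher_z)
  attr(out, "assignments") <- do.call(rbind, assignments)
  out
}
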