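---
title: "Models and methods for serial-scan connectivity reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for serial-scan connectivity reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcreliab)
```

## The three-level model

`fcreliab` treats each edge of a functional connectome as a repeatedly
measured quantity in a crossed design: participants $k = 1,\dots,K$ are
scanned in sessions $i = 1,\dots,I$, each session sampling every condition
$j = 1,\dots,J$ once. The observed edge value (Fisher-z by default) is

$$y_{ijk} = \mu + \delta_k + \gamma_{jk} + \varepsilon_{ijk},$$

with mutually independent zero-mean Gaussian effects
$\delta_k \sim N(0, \sigma_3^2)$ (stable participant differences),
$\gamma_{jk} \sim N(0, \sigma_2^2)$ (participant-by-condition interaction),
and $\varepsilon_{ijk} \sim N(0, \sigma_0^2)$ (session-level noise).
There is no fixed condition main effect in the default model: condition
enters only through the random $\gamma_{jk}$. This keeps the decomposition
symmetric across conditions; a shared condition shift would be absorbed into
$\sigma_2^2$, which is the interpretation we adopt.

Two intraclass correlations summarize the decomposition:

- **between-condition ICC** $= \sigma_3^2 / (\sigma_3^2 + \sigma_2^2)$ —
  how stable an edge is across conditions, relative to participant-level
  signal. The session-level residual is deliberately absent from the
  denominator, so this is a statement about the participant/condition
  hierarchy only. `icc_between_condition(vc, include_residual = TRUE)`
  offers the total-variance-normalized alternative
  $\sigma_3^2 / (\sigma_3^2+\sigma_2^2+\sigma_0^2)$ for users who want every
  ICC on the same denominator.
- **between-session (test–retest) ICC**
  $= (\sigma_3^2 + \sigma_2^2) / (\sigma_3^2 + \sigma_2^2 + \sigma_0^2)$ —
  the proportion of total variance that is reproducible across sessions.

## Estimation

**Method of moments (complete data).** For complete balanced panels the
nested mean squares have closed-form expectations
($E[MS_{error}] = \sigma_0^2$, $E[MS_{cell}] = \sigma_0^2 + I\sigma_2^2$,
$E[MS_{subject}] = \sigma_0^2 + I\sigma_2^2 + IJ\sigma_3^2$), giving the
ANOVA estimator of `anova_moments()`. Negative moment solutions are clamped
to zero and the clamping is recorded — at small $K$ the subject-level
component is the one most often clamped.

**REML (any missingness).** `fit_em_reml()` maximizes the restricted
likelihood with the grand mean profiled out. Because subjects are
independent, each subject contributes a small covariance block
$V_k = \sigma_0^2 I + Z_k D Z_k^\top$ that we handle through the Woodbury
identity ($Z_k$ has one subject column plus one column per observed
condition), so each evaluation costs a handful of $5\times 5$ factorizations
rather than anything scan-sized. The criterion is optimized over
log-variances (so estimates are nonnegative by construction) with the
analytic REML score supplied to L-BFGS-B; convergence is declared when the
scaled score is numerically zero, and boundary solutions below $10^{-7}$
times the response variance are reported as exact zeros. On complete
balanced panels with interior estimates the REML and moment estimators
coincide, which the test suite checks to $10^{-6}$ relative.

We chose direct score-based maximization over a literal EM iteration because
it reaches much tighter optima in far fewer likelihood evaluations; the two
are estimating the same REML stationary point. An independent mixed-model
implementation (`lme4`) is used in the test suite as a cross-check oracle on
incomplete panels, never as the estimator.

**Dispatch.** `fit_panel()` uses the vectorized moment path when the panel
is complete and per-edge REML otherwise. Missing scans are represented as a
mask on the panel, never dropped silently; `inject_missing()` refuses to
remove a subject entirely when only one condition exists.

**Per-condition ICC.** Restricting to one condition leaves the two-level
model $y_{ik} = \mu + b_k + e_{ik}$; `per_condition_icc()` fits it by the
same REML machinery and returns $\sigma_b^2/(\sigma_b^2+\sigma_w^2)$.

## I2C2 and fingerprinting

`i2c2()` implements the trace method-of-moments form of the image-level
intraclass correlation: one minus the ratio of pooled within-group to total
trace of the replicate vectors, clamped to $[0,1]$. With $p = 1$ it reduces
exactly to the univariate $1 - MSW/MST$. Two grouping choices matter:

- grouping replicates by **subject-by-condition cell** makes the stable part
  of a replicate $\delta_k + \gamma_{jk}$, so the estimand is the
  between-session ICC $(\sigma_3^2+\sigma_2^2)/(\sigma_3^2+\sigma_2^2+\sigma_0^2)$
  — this is the pooled design used in the consistency checks;
- grouping by **subject** while pooling scans across conditions moves
  $\sigma_2^2$ into the within-group trace, giving
  $\sigma_3^2/(\sigma_3^2+\sigma_2^2+\sigma_0^2)$ instead.

`i2c2_by_network()` computes the estimator per network block. A network's
block defaults to every edge *incident* to it (any edge whose ROI pair
involves the network), matching network-wise displays in which interactions
count toward both networks; `block_mode = "within"` restricts to edges fully
inside the network.

Fingerprinting (`similarity_matrix()`, `within_between_stats()`) correlates
whole-connectome edge vectors between scans and contrasts same-subject with
different-subject pairs. Similarity is computed on raw `r` or Fisher-z
edges as supplied; the confidence interval is the normal approximation
$\bar x \pm 1.96\, s/\sqrt{n_{pairs}}$, recorded together with the pair
count, since with $>10^4$ pairs the interval is dominated by the pair count.
By default all same-subject pairs are pooled across sessions and conditions;
`stratum = "same_condition"` / `"same_session"` restrict the comparison.
`identify_subjects()` adds nearest-neighbour identification with ties broken
toward the lowest scan index.

## Connectivity and preprocessing choices

- Motion confounds use the standard 24-parameter expansion: the six
  parameters, squares, backward differences (first row zero — the
  difference stencil is not specified more finely by common usage, and the
  zero-row convention keeps the design full length), and squared
  differences.
- `nuisance_regress()` removes an intercept, orthogonal polynomial trends
  (order 2 by default), and any confounds by OLS; exactly collinear columns
  are dropped with a warning naming them.
- Edges are the strict upper triangle, ordered by unordered network pair —
  blocks follow a fixed canonical network list (visual, somatomotor, dorsal
  attention, ventral attention, limbic, frontoparietal, default,
  no-overlap) — then by ascending ROI index; the ordering is a pure
  function of the partition, so vectors are comparable across scans. Edge
  labels are orientation-canonicalized so permuted ROI input yields the same
  label set.
- Fisher z is applied before model fitting by default (unbounded support
  suits the Gaussian model); fingerprint similarity accepts either. At
  $|r| = 1$ the transform is undefined and errors unless clipping at
  $1 - 10^{-7}$ is requested.

## The synthetic-data generator

`simulate_edge_panel()` draws every edge independently from the three-level
model, returning the effect draws so estimators can be validated against a
recoverable truth. Defaults emulate the serial-scanning design the package
targets: 10 subjects, 4 conditions, 12 sessions, variance components
$(\sigma_3^2, \sigma_2^2, \sigma_0^2) = (0.04, 0.01, 0.10)$ in Fisher-z
units around a mean edge strength of 0.3 — values in the range typical of
edge-level connectivity, with session noise dominating and a true
between-condition ICC of 0.80 and between-session ICC of 1/3. The
missingness helper mirrors the realistic pattern of three subjects each
missing one task session.

`simulate_timeseries_panel()` makes the structure observable end to end: a
scan's target correlation matrix is the shared base matrix plus the scan's
effect draws in Fisher-z space, mapped back through `tanh` and projected to
the nearest positive-definite correlation matrix (eigenvalue clipping at
$10^{-8}$, then unit-diagonal rescaling — deterministic and standard);
Gaussian series are sampled through the Cholesky factor. Per-scan RNG
streams are derived by stable integer hashing of (seed, subject, condition,
session), so output does not depend on generation order. Estimating $r$
from $T$ finite timepoints adds sampling noise of order $1/\sqrt{T}$ on top
of $\sigma_0^2$; the default $T = 414$ corresponds to a 10-minute scan at
TR 1.45 s.

What the generator does **not** emulate: cross-edge covariance (edges are
independent by default), temporal autocorrelation within scans, head-motion
artifacts, non-Gaussian tails, or condition mean shifts. Passing tests
therefore demonstrate estimator correctness under the stated model, not
robustness to those realities.

## Scan duration and pseudo-sessions

`duration_pseudosessions()` asks how reliability changes when each replicate
contains more data while the number of replicates stays fixed: per subject
and condition, sessions are sampled without replacement into four disjoint
groups, each group's series concatenated and correlated. Longer
pseudo-sessions average session-level effects ($\sigma_0^2/m$ for $m$
concatenated sessions, approximately) and shrink sampling noise, so
per-condition ICC medians rise with duration — the qualitative signature
the package reproduces on synthetic data at 10/20/30 minutes.

## Counterbalanced schedules

`generate_schedule()` builds session orders in which every session contains
each condition once, each condition occupies each slot equally often, each
condition is preceded by each other condition equally often (within-session
transitions), and each non-rest condition's three stimulus exemplars rotate
exactly once per three-session block. The search is randomized backtracking
over session rows with slot/predecessor count propagation and a bounded
restart budget (default 10,000), deterministic per seed; the 12-session,
4-condition default yields slot and predecessor counts of exactly 3.
Exemplar orderings vary across participants via a per-subject seed offset
rather than a hard parity rule, since only the constraint — not a specific
ordering — defines the design. `verify_schedule()` recounts every
constraint independently of the generator.

## Scalar quality measures

`scalar_measure_reliability()` applies the two-level ICC per measure and
condition, and a one-way ANOVA of condition on scan-level values. The
ANOVA's unit of observation is the scan by default (subject-mean variant by
flag); on null data its type-I error sits at the nominal 5%, which the test
suite verifies over 1000 replicates.

## Numerical conventions and limitations

- Percentiles use linear interpolation between order statistics
  (`quantile` type 7).
- All reported ICCs lie in $[0,1]$; clamping events are recorded on the
  component objects.
- Variance components below $10^{-7}$ times the response variance are
  reported as exact zeros; true boundary cases ($\sigma^2 = 0$) are
  recovered as such.
- Problem sizes in the shipped checks (up to 1000 edges for recovery
  studies, 12 ROIs / 414 timepoints for duration analysis, 1000 replicates
  for the type-I study) were chosen so each property is measured with
  comfortable Monte-Carlo margin while a full run stays interactive.
- No inferential uncertainty (confidence intervals on individual ICCs) is
  provided, and the pipeline starts at ROI time series: volumetric
  preprocessing, registration, and atlas extraction are out of scope.
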