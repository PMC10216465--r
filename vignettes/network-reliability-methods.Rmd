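---
title: "Methods: small-world metrics and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world metrics and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreliab)
```

## What the package computes

`netreliab` asks a practical question about graph-theoretical analysis of
resting-state functional connectivity: *how stable are small-world network
metrics when the same brain is scanned repeatedly, and how does that
stability depend on the processing strategy?* The pipeline covers the whole
chain:

1. **ROI time series → connectivity.** Pearson correlation between regional
   time courses, optionally after global signal regression (GSR): the mean
   signal across regions is removed from each regional series by ordinary
   least squares.
2. **Connectivity → networks.** Proportional-density thresholding: the
   strongest fraction `d` of positive correlations becomes the edge set,
   binarised or kept as weights. Global metrics are computed on a density
   grid of 0.15–0.35 (step 0.05); nodal metrics on 0.05–0.50 (step 0.05)
   and summarised as the trapezoidal area under the metric–density curve
   (AUC).
3. **Networks → metrics.** Seven global metrics — clustering coefficient
   `Cp`, characteristic path length `Lp`, their null-normalised versions
   `gamma` and `lambda`, small-worldness `sigma = gamma / lambda`, global
   efficiency `Eg`, local efficiency `Eloc` — and three nodal metrics —
   degree `Dc`, betweenness `Bc`, nodal efficiency `Ne`.
4. **Metrics → reliability.** The single-measure absolute-agreement
   intraclass correlation
   `ICC(A,1) = (BMS − EMS) / (BMS + (k−1) EMS + (JMS − EMS) k/n)` from the
   two-way random-effects decomposition of the subjects × sessions table,
   plus the within-subject coefficient of variation `CV = S/M` (sample SD
   over mean, reported in percent).
5. **Reliability → comparisons.** Paired t-tests between strategies,
   one- and two-way repeated-measures ANOVAs with Greenhouse–Geisser (GG)
   correction, Bonferroni post hocs, and a between-groups ANOVA over nodes.

Eight strategies are crossed from three binary toggles: binary vs weighted
edges (`B`/`W`), GSR vs none (`G`/`NG`), and 90 vs 264 regions — `BG90`,
`BNG90`, `WG90`, `WNG90`, `BG264`, `BNG264`, `WG264`, `WNG264`.

## The synthetic multi-session generator

No public scans accompany the design the package emulates, so
`simulate_study()` generates the study: `n_subjects = 16`, `n_sessions = 3`,
`n_timepoints = 210` per scan, at 90 or 264 ROIs. The generative model works
on the Fisher-z scale, where additive variance components are well defined
and the ground-truth edgewise reliability is known:

* a population matrix with mean `base_connectivity = 0.25` and edge
  heterogeneity SD `sigma_edge = 0.15`;
* an anticorrelated system covering `anticorr_fraction = 0.2` of ROIs whose
  between-system edges are reduced by `anticorr_strength = 0.6` — the
  task-positive/task-negative organisation that gives connectomes their
  negative tail;
* per-subject symmetric deviations with SD `sigma_between = 0.12` (trait
  signal) and per-session deviations with SD `sigma_within = 0.06` (state
  noise), so the latent edgewise ICC before sampling noise is
  `0.12² / (0.12² + 0.06²) = 0.8`, eroded towards realistic mid-range values
  by correlation sampling error at 210 timepoints (z-scale variance
  ≈ 1/207);
* back-transformation to correlations with a deterministic
  nearest-correlation repair (eigenvalues clipped at 1e-8, rescaled to unit
  diagonal);
* stationary AR(1) sampling with `ar1_coef = 0.3`, mimicking the temporal
  smoothness of band-passed BOLD without implementing filtering;
* a shared scalar AR(1) global signal with SD `global_amplitude = 0.5`
  relative to the unit ROI signal, giving GSR something real to remove.

The variance components were fixed once as field-plausible values; none is
calibrated to reproduce any published reliability number. Each
subject-session draws from its own RNG stream,
`(seed + 100003·subject + 1009·session) mod (2³¹−1)`, so single items can be
regenerated independently and full runs are byte-reproducible.

What the generator does **not** emulate: head motion, physiological noise,
scanner drift, spatial autocorrelation between neighbouring ROIs,
heterogeneous regional variances, or any voxel-level structure. Passing
tests therefore demonstrate that the *pipeline* measures what it should on
data with known truth — not that any particular strategy is superior on
real scans.

## Why densities near 0.5 need special handling after GSR

GSR residuals sum to zero across regions at every timepoint, which forces
the *mean* post-GSR edge covariance to be negative; empirically the
correlation distribution re-centres near zero and only about half the edges
stay positive. Since negative correlations are never admitted as edges
(they would break `1/weight` path lengths and have no standard
interpretation as connection strength), a proportional threshold of 0.50
can exceed the positive supply. `proportional_threshold()` fails loudly in
that case by default, reporting the achievable maximum. The pipeline's
nodal sweep alone opts into `partial = TRUE`: the network is capped at the
achievable density and flagged (`capped`), matching how practitioners'
toolboxes behave at high densities under GSR. The global grid (≤ 0.35) is
always comfortably feasible and errors if ever capped.

## Numerical and algorithmic choices

* **Edge ranking.** Round-half-up edge counts
  (`m = floor(d · N(N−1)/2 + 0.5)`); ties broken by ascending (row, column)
  index — deterministic across platforms. Thresholding is rank-based, hence
  invariant to any strictly increasing transform of the positive
  correlations (no Fisher-z is applied before thresholding; the choice is
  recorded in the run metadata).
* **Distances.** Binary graphs use breadth-first hop counts; weighted
  graphs use Dijkstra with edge length `1/weight`. Unreachable pairs are
  infinite; `Lp` averages the finite pairs and reports the disconnected
  fraction instead of substituting an arbitrary constant; efficiencies
  handle disconnection natively (`1/∞ = 0`). Shortest-path kernels are
  compiled (C++) because the local-efficiency subgraph sweep and the null
  ensemble dominate runtime.
* **Weighted clustering.** Onnela's form: geometric mean of triangle
  weights after normalising by the network maximum, with binary degree in
  the denominator; nodes with fewer than two neighbours get `C_i = 0`.
* **Betweenness.** Brandes' algorithm (igraph), fractional credit across
  tied shortest paths, endpoints excluded, unnormalised counts (ICC is
  scale-invariant, so normalisation is irrelevant downstream).
* **Null ensemble.** Degree-preserving double-edge swaps, 10·|E| attempted
  swaps per surrogate, `n_random = 100` by default; weighted surrogates
  additionally receive a random permutation of the original weight multiset
  over the rewired topology, preserving both the degree sequence and the
  weight multiset. `gamma = Cp/⟨Cp_rand⟩`, `lambda = Lp/⟨Lp_rand⟩`,
  `sigma = gamma/lambda` by construction. A warning is raised when swaps
  fail to move the edge set for most surrogates (pathological degree
  sequences such as complete graphs).
* **ICC reporting.** The signed estimate `icc_raw` is kept for diagnostics;
  the reported `icc` is clamped to `[0, 1]` (reliability tables
  conventionally floor at 0.000). Qualitative bands: `< 0.25` poor,
  `0.25–0.4` low, `0.4–0.6` fair, `0.6–0.75` good, `0.75–1` excellent;
  boundary values belong to the higher band. The ANOVA estimator carries a
  finite-sample downward bias of order `1/n` (≈ 0.02 at n = 16, k = 3 for
  mid-to-high reliability); it is a property of the estimator, not of the
  implementation, which agrees with a literal sums-of-squares oracle to
  1e-12.
* **CV.** Sample (k−1) standard deviation; undefined (error) when a
  subject's mean is zero — metrics here are positive, so this only guards
  degenerate input.
* **Repeated-measures ANOVA.** Explicit sums of squares; GG epsilon per
  effect from the covariance of (orthonormal-contrast) within-subject
  scores, bounded to `[1/(p−1), 1]`; corrected fractional degrees of
  freedom are reported. Cross-checked in the test suite against
  `car::Anova`. Zero-effect layouts return `F = 0` rather than `0/0`.
* **Pooling conventions.** Strategy t-tests pool the 7 metrics over the 4
  strategy pairings that differ only in the toggle under test (df 27); the
  interval-by-method ANOVA uses the 7 metrics as cases over 3 visit pairs ×
  4 method families (atlas variants averaged; interaction df 6, 36); the
  nodal strategy ANOVA treats nodes as observations (4·90 + 4·264 = 1416
  cells, error df 1408); subgroup t-tests pool 7 metrics × 8 methods
  (df 55). These conventions are frozen so the design-level degrees of
  freedom are well defined.

## Problem sizes used by the shipped checks

The unit tests run the pipeline on miniature designs (6 subjects, 24–30
ROIs) so the whole suite stays fast; the acceptance suite runs the full
16 × 3 × 210 design at both atlas sizes with the null ensemble reduced to
20 surrogates per network, which leaves the ensemble means noisy but
unbiased and keeps the full eight-strategy sweep in the minutes range on a
single CPU. Oracle equivalence is checked by exhaustive enumeration
(all simple paths, brute-force triangles, literal sums of squares) on
graphs of up to 8 nodes, where enumeration is exact and cheap.

## Known limitations

* Subject and session deviations are independent across edges, as the
  generative model defines them. Independent edgewise differences largely
  cancel when thousands of edges are summarised into one global metric,
  while structured session-specific noise (sampling error interacting with
  the correlation-matrix repair and the global signal) does not — so
  global-metric ICCs in simulation sit below the edgewise reliability and
  below values typical of real cohorts, where individual differences are
  system-level and survive aggregation. Comparisons *between* strategies,
  the package's subject matter, are unaffected.
* Session deviations are exchangeable — there is no built-in drift with
  inter-scan interval, so pairwise-visit reliabilities differ only by
  sampling noise in simulated data.
* Subject covariates (sex, age) are synthesised labels unrelated to the
  connectivity process; subgroup analyses exercise the machinery, not a
  biological hypothesis.
* The nearest-correlation repair slightly perturbs extreme latent matrices,
  so stated variance components are exact only up to that projection and
  the tanh back-transform.
* Weighted `gamma` compares Onnela clustering against weight-permuted
  surrogates; other weighted null conventions exist and would shift
  `gamma`/`sigma` scales, though not their ordering across strategies.

## A worked miniature example

```{r example, eval = FALSE}
library(netreliab)
library(dplyr)

res <- run_study(
  sim_config(n_subjects = 8, n_sessions = 3, n_timepoints = 120, seed = 1),
  methods     = method_specs(c("BG90", "BNG90", "WG90", "WNG90")),
  global_grid = density_grid(0.15, 0.35, 0.05),
  nodal_grid  = density_grid(0.05, 0.50, 0.05),
  n_random    = 20
)

res$reliability_global |> filter(density == "mean")
res$comparisons$strategy_ttests
autoplot(res, "global")
```
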