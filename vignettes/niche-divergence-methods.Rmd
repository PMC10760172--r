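---
title: "Methods: presence-background niche models and niche-overlap permutation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche models and niche-overlap permutation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Stable hybrid zones can be maintained by qualitatively different balances of
selection and dispersal. Under a *tension zone*, selection against hybrids is
endogenous and the zone's position is environment-independent; under a
*geographical selection gradient*, exogenous selection acts against hybrids
along an environmental gradient; under *bounded superiority*, exogenous
selection favors hybrids inside a transitional niche occupied by neither
parent. The three hypotheses make distinct predictions about the realized
environmental niches of the parental forms and the hybrids: no divergence
anywhere, divergence between parents only, or divergence among all three
groups. `nichekit` estimates those niches from presence-only occurrence
records with a maximum-entropy model, quantifies pairwise niche overlap, and
attaches permutation-based significance to the overlap statistics.

## Occurrence preparation

Citizen-science checklists vary enormously in effort, and effort correlates
with environment. Three standard corrections are applied before modelling:

* **Checklist filtering** (`filter_records()`). Records are kept only when
  the checklist looks like a bounded, complete survey: Stationary or
  Traveling protocol, duration strictly under 360 minutes, distance traveled
  strictly under 10 km, start time between 06:00 and 21:00 inclusive, at
  most 10 observers, completeness flag set, June–July, 2010–2023, and (for
  geographic data) the north-east Pacific extent 175°W–114°W, 31°N–62°N.
  The strict-vs-inclusive choices follow the criteria exactly as
  conventionally printed (`< 360`, `< 10`, `<= 10`); boundary records at 360
  minutes are therefore rejected while 10-observer records are kept. Each
  dropped row is attributed to its *first* failed criterion in a fixed
  documented order (protocol, duration, distance, time, observers,
  completeness, month, year, bbox); the order affects only the rejection
  bookkeeping, never the retained set.
* **Spatial thinning** (`thin_spatial()`, default minimum distance 0.5 km).
  We implement distance-based thinning — repeat a randomized greedy pass
  that removes the point with the most neighbours closer than the minimum
  distance until no conflict remains, keep the largest set over `n_repeats`
  restarts — rather than grid-cell thinning, because the distance guarantee
  dominates the grid guarantee (any distance-thinned set is also valid for
  the corresponding grid) and matches the behaviour of the thinning tools
  this workflow standardizes on. A grid-based alternative remains available
  behind `thin_config(method = "grid")`. Great-circle distances use the
  haversine formula with mean Earth radius 6371.0088 km; synthetic planar
  landscapes are tagged as km-unit grids and use Euclidean distances
  consistently.
* **Balancing and background** (`balance_groups()`, default 1500 per group;
  `target_group_background()`, default 10 000 points). Balancing samples
  uniformly without replacement, independently per group. Background points
  are drawn from the filtered-and-thinned *all-species* table so that they
  carry the same spatial sampling-effort signature as the presences — the
  target-group background correction for presence-background models.

An explicit id-blacklist is the only outlier-removal mechanism offered; we
do not attempt to reproduce any manual outlier screening, since no rule for
it can be stated.

## Variable selection

Collinear environmental layers distort variable-importance estimates.
`compute_vif()` defines `VIF_j = 1/(1 - R²_j)` with `R²_j` from an ordinary
least-squares regression of layer *j* on all other candidate layers plus an
intercept; exact collinearity is reported as `Inf`. Two established greedy
procedures are provided: `vifstep_select()` (drop the largest VIF while it
exceeds 10, recompute) and `vifcor_select()` (while any pair correlates
beyond |r| = 0.9, drop the pair member with the larger current VIF,
recompute). Because a workflow that runs both must reconcile them somehow
and no canonical order exists, `select_variables()` reports each method's
pure result and retains their **intersection** — the conservative choice
that satisfies both stopping rules. Ties are broken alphabetically so
reports are reproducible. Categorical layers are excluded from the VIF
computations (linear VIF is undefined for unordered class codes) but are
always retained for modelling.

## The maximum-entropy model

Let `f(x)` be a feature vector derived from the environment at location `x`,
and let the background cells define the available environment. The model is
the Gibbs distribution over background cells

`q_lambda(i) = exp(lambda · f(i)) / Z_lambda`

maximizing the L1-penalized training gain

`G(lambda) = mean_presence(lambda · f) - log mean_background(exp(lambda · f)) - sum_j beta_j |lambda_j|`,

with `beta_j = beta * s_j / sqrt(m)` (`s_j` the feature's presence-sample
standard deviation, `m` the presence count, multiplier `beta = 1` by
default). The gain is measured relative to the uniform background
distribution, so it starts at zero and its per-update increments are
interpretable; this differs from the unnormalized log-likelihood objective
only by the constant `log n_background` and has the same maximizer.

Numerical choices:

* **Features.** Default classes are linear + quadratic on continuous
  variables and one-hot indicators on categorical ones, min-max scaled to
  [0, 1] using the combined presence + background extremes (new data is
  clamped to that range). Product and hinge features exist
  (`build_features(classes = ...)`) but are off by default: the small
  default basis keeps the optimization easily checkable against brute-force
  oracles and is adequate for smooth unimodal niches. Hinge knots sit at
  presence-value quantiles.
* **Solver.** Cyclic coordinate ascent (compiled): per coordinate a Newton
  step on the smooth part, soft-thresholded for the L1 penalty, with step
  halving so the penalized gain never decreases — the trace asserts this.
  Convergence is declared when a full cycle improves the gain by less than
  `tolerance` (default 1e-7). A regularization floor of `s_j >= 1e-6`
  prevents a zero penalty on features constant across presences. A
  (near-)constant feature under the current background distribution is
  skipped unless the penalty alone moves it. Non-convergence within
  `max_iter` returns a model flagged `converged = FALSE` rather than an
  error.
* **Outputs.** `raw` is `exp(eta)/Z` with `Z` the sum over the *training
  background*, so raw output sums to 1 when predicted at the background and
  the overlap statistics can treat maps as probability distributions after
  renormalization; `cloglog` is `1 - exp(-exp(H) * raw)` with `H` the
  entropy of the fitted background distribution, a monotone transform used
  for response curves. Overlap statistics always consume raw output.

**Validation** (`crossvalidate()`) uses replicated random 80/20 presence
splits (default 10 replicates) — repeated subsampling, not disjoint
10-fold — and never splits the background. AUC is the Mann–Whitney
statistic with mid-rank ties, so it is invariant under monotone transforms
of the scores; 0.7 is the conventional reliability bar. **Percent
contribution** sums the positive gain increments of trace updates per
source variable (path-dependent by construction, as the measure is
conventionally defined); **permutation importance** permutes one variable's
raw values across all rows, rebuilds only that variable's features with the
stored scalings, and normalizes the positive AUC drops to 100%.

## Overlap statistics and permutation tests

With both suitability maps renormalized over the intersection of their
valid cells (`p_X`, `p_Y`):

* Schoener's `D = 1 - 0.5 * sum_i |p_X,i - p_Y,i|`
* Hellinger `H = sqrt(sum_i (sqrt(p_X,i) - sqrt(p_Y,i))²)`
* Warren's `I = 1 - H²/2 = sum_i sqrt(p_X,i * p_Y,i)` (Bhattacharyya
  coefficient).

The canonical square-root forms are used; they guarantee `0 <= D <= I <= 1`
(total variation is at least half the squared Hellinger distance), a
property the test suite checks on a thousand random pairs, and both
algebraic forms of `I` are verified to agree to 1e-12.

The **identity test** pools the two groups' occurrences, repeatedly
repartitions the pool at random into pseudo-groups of the original sizes,
and *refits both models per replicate* with identical settings and the same
background — resampling model predictions instead of refitting would not
propagate the label permutation through the model. One deliberate economy:
feature scaling constants are computed once from the pooled data and reused
across replicates, so null refits differ only in presence labels; scalings
are dominated by the shared background extremes, and holding them fixed
removes a source of spurious inter-replicate variation. The **blob
range-breaking test** replaces the random split by a spatially contiguous
one: a pooled point is chosen uniformly as origin and the `|A|` nearest
points (ties broken by point id) form pseudo-A.

P-values use the add-one convention `p = (1 + #{null <= obs}) / (n_iter + 1)`
with ties counted toward the tail, so `p >= 1/(n_iter + 1)` and the test is
valid at finite `n_iter` (default 100). Niche divergence is the *lower*
tail (observed overlap below the randomized controls); both tails are
always reported, because for range-breaking tests the interesting direction
depends on whether one asks about a boundary (lower) or about mosaic
structure (upper), and published usage is not consistent. A null replicate
whose refit fails to converge is redrawn once and otherwise excluded, with
the exclusion count reported.

## The synthetic-data module

The generator provides the statistical structure the analysis assumes,
without external downloads:

* **Landscapes** are Gaussian random fields: white noise convolved with a
  separable Gaussian kernel (circular boundary), standardized, so the
  effective correlation length approximately equals the kernel bandwidth.
  Inter-layer correlation is induced by linearly mixing independent latent
  fields through the matrix square root of the target correlation matrix —
  exact targets are approximate by design and recovered within ±0.05 on a
  200 × 200 grid. Spectral synthesis would give finer control of the
  covariance function but is unnecessary for these tests. Categorical
  layers quantile-threshold a latent field into equal-area classes.
* **Niches** are products of independent Gaussian responses per continuous
  layer times per-class weights on categorical layers — no interactions, so
  every ground truth is analytically checkable. `make_scenario()` encodes
  the three study designs: `identical` (the null), `divergent` (optima
  `separation · sigma` apart on one axis), and `three_group` (parents at
  `±separation/2` on axis 1, hybrid offset by `separation/2` on axis 2 — a
  genuinely distinct niche, not an intermediate one, which is what the
  bounded-superiority hypothesis posits).
* **Occurrences** are multinomial draws over cells with probabilities
  proportional to suitability (conditioned on `n`; not an inhomogeneous
  Poisson process — downstream methods only use point locations), with
  optional uniform within-cell jitter.
* **Checklist metadata** is drawn from distributions that satisfy every
  filter; a configurable fraction of records per criterion is planted to
  violate it, and the generator's ledger records exactly which ids, so
  filter tests have exact expectations.

What the generator does *not* emulate: sampling-effort bias surfaces (the
workflow corrects for effort, it does not simulate it), migration and
seasonal movement, detection probability, and spatial aggregation beyond
what the smooth suitability surface induces. Passing tests therefore
demonstrate correctness of the algorithms under these idealized conditions,
not robustness to every pathology of real checklist data.

## Reproducibility and problem sizes

Every generator and test is a pure function of its arguments and a seed;
`run_pipeline()` derives per-stage seeds from the master seed by hashing
the stage name, so adding a stage never perturbs earlier stages'
randomness, and two runs with the same configuration produce byte-identical
JSON reports.

The packaged test suite and the acceptance script run everything at desk
scale, chosen so the full statistical battery (including 200 replicated
identity tests for type-I calibration and 50 for power) completes in
minutes on one core: landscapes of 40–80 cells per side, 100–400 presences
per group, 300–1500 background points, 99 null iterations in simulation
batteries and the conventional 100 in the default pipeline. The defaults
that correspond to study-scale constants — 0.5 km thinning, 1500 records
per group, 10 000 background points, VIF threshold 10, |r| threshold 0.9,
10 × 80/20 validation, 100 permutation iterations, alpha 0.05 — are kept at
those values.

## Known limitations

* The identity and blob tests inherit maxent's sensitivity to background
  choice; holding the background fixed across observed and null fits
  isolates the occurrence-label effect but cannot correct a biased
  background.
* Percent contribution is path-dependent; permutation importance is the
  more robust measure and the one used for cross-model comparisons.
* Distance-based thinning is a greedy heuristic; it matches the brute-force
  optimum on all small instances in the test suite but carries no general
  optimality guarantee.
* Raster support is deliberately minimal (in-memory stacks and ESRI ASCII
  interchange); projection handling beyond lon/lat vs planar-km tagging is
  out of scope.
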