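# nichekit

Presence-background niche models and niche-overlap permutation tests for
hybrid-zone analysis.

## What problem this solves, and for whom

When two related taxa meet and hybridize, the stability of the resulting
hybrid zone can be maintained by very different mechanisms — a *tension
zone* (endogenous selection against hybrids, environment-independent), a
*geographical selection gradient* (exogenous selection against hybrids
along an environmental gradient), or *bounded superiority* (exogenous
selection favoring hybrids in a transitional niche occupied by neither
parent). These hypotheses predict, respectively: no niche divergence
anywhere, divergence between the parental forms only, or divergence among
all three groups.

`nichekit` is for ecologists who want to discriminate between those
predictions from presence-only occurrence records (eBird-style checklists)
and gridded environmental layers. It provides the full workflow:

1. **Occurrence preparation** — checklist-quality filtering (protocol,
   duration < 360 min, distance < 10 km, 06:00–21:00, ≤ 10 observers,
   complete checklists, season/years, study extent), spatial thinning to a
   0.5 km minimum distance, per-group balancing, and target-group
   background selection to cancel sampling-effort bias.
2. **Variable selection** — variance-inflation-factor procedures
   (`vifstep`, threshold 10; `vifcor`, |r| threshold 0.9) with the
   intersection of their retained sets.
3. **Niche modelling** — an L1-regularized maximum-entropy
   (maxent-style) model fit by coordinate ascent (compiled core): the Gibbs
   distribution over background cells `q(i) ∝ exp(λ·f(i))` maximizing the
   penalized gain `mean_presence(λ·f) − log mean_background(e^{λ·f}) −
   Σ β_j|λ_j|`, with replicated 80/20 AUC validation, percent contribution,
   permutation importance, and response curves.
4. **Niche overlap** — Schoener's `D = 1 − ½Σ|p_X − p_Y|`, Hellinger
   `H = √(Σ(√p_X − √p_Y)²)`, Warren's `I = 1 − H²/2` over normalized
   suitability maps.
5. **Significance** — the niche **identity test** (pool both groups,
   randomly repartition, refit both models per replicate) and the **blob
   range-breaking test** (contiguous splits around a random origin), with
   add-one one-tailed p-values.
6. **Synthetic data** — spatially autocorrelated landscapes with
   controllable inter-layer correlation, Gaussian niche-response surfaces,
   multinomial occurrence sampling and checklist metadata with planted,
   ledgered filter violations — so the whole pipeline is testable without
   downloads.

## Worked example

Two groups four niche breadths apart on a synthetic landscape:

```r
library(nichekit)

grid   <- grid_spec(60, 60, crs = "planar")
layers <- list(layer_spec("temperature",   autocorr_length = 5),
               layer_spec("precipitation", autocorr_length = 5))
land   <- generate_landscape(grid, layers,
                             correlation = matrix(c(1, .3, .3, 1), 2), seed = 1)

scen <- make_scenario("divergent", separation = 4,
                      layer_names = c("temperature", "precipitation"))
occA <- sample_occurrences(gaussian_niche_suitability(scen, "groupA", land),
                           200, group = "groupA", seed = 2)
occB <- sample_occurrences(gaussian_niche_suitability(scen, "groupB", land),
                           200, group = "groupB", seed = 3)

effort <- suitability_grid(grid, matrix(1, 60, 60))   # uniform survey effort
bg <- as.data.frame(sample_occurrences(effort, 500, group = "bg", seed = 4))[
  , c("longitude", "latitude")]

feats <- build_features(extract_env(land, occA), extract_env(land, bg))
crossvalidate(feats, n_replicates = 10, seed = 5)
#> <eval_result> 10 replicate(s): mean AUC 0.806 (SD 0.028)

fitA <- fit_maxent(feats)
fitB <- fit_maxent(build_features(extract_env(land, occB),
                                  extract_env(land, bg)))
ov <- overlap_stats(predict_suitability(fitA, land, "raw"),
                    predict_suitability(fitB, land, "raw"))
sprintf("D = %.3f, H = %.3f, I = %.3f", ov$D, ov$H, ov$I)
#> "D = 0.307, H = 0.913, I = 0.583"

identity_test(occA, occB, land, bg, test_config(n_iter = 99, seed = 6))
#> <permutation_test_result> identity test: groupA vs groupB (99 null replicates)
#>   D = 0.3075  (p_lower = 0.0100, p_upper = 1.0000)
#>   I = 0.5829  (p_lower = 0.0100, p_upper = 1.0000)
```

The validation AUC (0.81) clears the conventional 0.7 reliability bar, so
the models rank presences above background reliably. The overlap between
the two suitability maps is low (`D` = 0.31, `I` = 0.58), and the identity
test places the observed overlap below all 99 randomized-control refits
(`p` = 1/100, the minimum attainable at 99 iterations): the two groups'
niches are significantly divergent. `D` weighs probability mass
differences linearly and `I` quadratically, so `D ≤ I` always — both are
reported because they respond differently to disjoint high-suitability
regions.

The full pipeline — three groups (two parents + hybrid), all pairwise
overlaps, identity and blob tests — runs from one configuration:

```r
report <- run_pipeline(pipeline_config(master_seed = 42), outdir = "out")
```

or from a shell via the bundled wrapper:

```sh
Rscript inst/cli/nichekit.R run --config run.yaml --seed 42 --outdir out/
```

## Layout

- `R/`, `src/` — implementation (the maxent solver core is Rcpp)
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles (exhaustive thinning optimum, generic convex-solver maxent
  oracle, greedy VIF replays)
- `vignettes/niche-divergence-methods.Rmd` — the methods vignette: model
  definitions, defaults and their rationale, numerical choices, synthetic
  generator scope, limitations
- `inst/cli/nichekit.R` — shell entry point
- `scripts/acceptance.R` — end-to-end reproduction script
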