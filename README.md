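# urbanfelid

Tools for quantifying interspecific interactions between a dominant and a
subordinate carnivore — think puma (*Puma concolor*) and bobcat
(*Lynx rufus*) — from motion-activated camera data, across gradients of
residential development. The package is aimed at wildlife ecologists who
have per-site photo records and want the full chain from raw timestamps to
ranked occupancy models and activity-overlap estimates, with a built-in
synthetic-data generator so every stage can be validated against known
truth.

## What it computes

**Detection histories.** Photographs are collapsed into independent events
(a new event requires > 1 h since the last retained event of that species
at that site, unless a different marked individual is shown; dependent
young are excluded). Events are binned into noon-to-noon daily occasions,
optionally pooled into longer occasions, with effort (operating days)
tracked per site-occasion and missing cells distinguished from
non-detections.

**Single-species occupancy.** The single-season likelihood with imperfect
detection,

    L_i = psi_i * prod_t p_it^y_it (1 - p_it)^(1 - y_it) + (1 - psi_i) * I(no detection at i),

with logit-linked covariates on detection: site covariates (kernel-density
human development `HD`, grid membership `G`, dominant-species photo count
`PumaCount`), occasion covariates (`P1`–`P4` lag indicators marking the
day of a dominant-species detection plus 0–3 following days, effort `E`)
and `G*Pk` interactions. Fitting is direct maximum likelihood (BFGS,
multiple starts), with delta-method intervals for detection predictions.

**Conditional two-species occupancy.** The eight-parameter
dominant/subordinate parameterization (psiA, psiBA, psiBa, pA, rA, pB,
rBA, rBa) with the standard constraint sets (psiBA = psiBa;
pB = rBA = rBa; and their conditional relaxations), covariates on any
detection group, and a degenerate-dominant diagnostic for the known
failure mode when psiA is estimated at the boundary.

**Model selection.** AICc (`-2logL + 2K + 2K(K+1)/(n-K-1)`), Delta-AICc
and Akaike weights `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)`, with excluded
(non-convergent or degenerate) models ranked separately.

**Circadian activity overlap.** Von Mises kernel densities on the 24-h
circle with a plug-in bandwidth, the overlap coefficient
`Dhat = integral min(f, g)` (grid- and point-based estimators with the
conventional small/large-sample switch at n = 75), smoothed bootstrap
confidence intervals, and interval-overlap metrics for comparing two CIs.

**Synthetic surveys.** `sim_config()` / `simulate_detection_data()`
generate two-grid camera surveys (20 sites per 80 km² grid) with latent
two-species occupancy, a multi-day suppression of the subordinate species
after dominant visits on wildland grids, bimodal crepuscular activity
times, sub-hour photo bursts, and a human-structure surface — returning
the full latent truth for validation.

## Worked example

```r
library(urbanfelid)

cfg <- sim_config(suppression = 0, suppression_days = 3)  # wildland avoidance on
out <- run_pipeline(list(sim = cfg, n_boot = 1000), seed = 7)

out$fine          # fine-scale (daily) single-species model ranking
out$activity      # per-grid activity overlap with bootstrap CIs
```

A run with the default candidate sets prints a fine-scale comparison whose
top model carries the lag-by-grid interaction, e.g.

```
Model comparison (n = 40):
# A tibble: 6 x 7
  model                                 K  AICc delta_AICc   weight neg2loglik
1 psi(.), p(PumaCount+HD+G+P3+G*P3)     7 2458.        0    1.00e+0      2440.
2 psi(.), p(.)                          2 2532.       73.7  9.89e-17     2527.
...
```

meaning the avoidance signal written into the simulation (suppressed
subordinate detection for 3 days after a dominant visit, wildland grid
only) is recovered decisively by AICc, and

```
# A tibble: 2 x 6
  grid     delta_hat ci_low ci_high n_dominant n_subordinate
1 urban        0.800  0.699   0.887         49           225
2 wildland     0.740  0.643   0.818         53           202
```

gives each grid's estimated activity overlap between the two species with
smoothed-bootstrap 95% intervals.

The bundled reference tables from the motivating field study are available
via `study_model_rankings()`, `study_activity_overlap()` and
`study_photo_summary()` for benchmarking parsers, parameter counts and
weight recomputation.

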