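# cdmquant

Quantification of **collective directional migration (CDM)** of
multicellular clusters in 3D hydrogel assays.

Cancer cells seeded at 10–100 cells/mm³ in a gel sit hundreds of
micrometres apart, yet over 1–3 weeks they can coalesce into large
aggregates. The central question is *how*: by random (Brownian) cluster
motion with merging on chance contact, or by directed migration of
clusters toward one another. The two mechanisms leave opposite fingerprints
in the kinetics of the object count n(t) per field of view:

- **Random motion** makes coalescence a collision process
  (Smoluchowski coagulation), so the halving time t½ — the time at which
  n(t) reaches half its initial fitted value — scales inversely with
  seeding density ρ: slope β = −1 on log–log axes.
- **Directed migration** decouples t½ from ρ: β ≈ 0.

`cdmquant` implements the full analysis: sigmoid fitting of count series
(n(t) = b + (n₀−b)/(1+e^((t−t_m)/s))) with derived halving time, lag time
and density fraction φ = (n₀−b)/n₀; the log–log density-scaling test with
a directed / random / indeterminate classification; pseudo-volume growth
fits (A·2^(t/τ), doubling time T_d = 2τ/3); extended-depth-of-field
projection of z-stacks by local-variance maximisation; bulk/protrusion
segmentation, <50 µm small-object filtering and object counting;
cross-correlation frame alignment and symmetric-difference area
velocities; cytokine-array threshold selection and transwell
fold-over-control Welch statistics — plus an agent-based simulator of the
assays (directed chemotaxis vs Brownian motion, growth, contact merging)
and a microscopy-like z-stack renderer that provide ground truth for every
stage.

## Worked example

Simulate one directed assay at a realistic seeding density, fit its
kinetics, and run the density-scaling test on a replicated random-motion
experiment:

```r
library(cdmquant)

tr <- run_assay(sim_config(density = 31, mode = "directed",
                           duration = 14, seed = 7))
tr
#> <assay_truth> 43 seed objects -> 1 after 14 d | 42 merges

fit_count_sigmoid(count_series(tr))
#> <sigmoid_fit> converged | n0 = 76.84 b = 0 t_m = 0.8384 d s = 3.8 d
#>   t_half = 0.8384 d | t_lag = 0.8384 d | density fraction = 1

aggregating_fraction(tr)
#> [1] 1

glance(fit_growth(data.frame(time_days = 0:15,
                             area_um2 = 100 * 2^(0:15 / 3))))
#> # A tibble: 1 × 5
#>      A0   tau   T_d resid_rms  nobs
#>   <dbl> <dbl> <dbl>     <dbl> <int>
#> 1  100.     3     2  6.45e-16    16

ex <- scaling_experiment("random", replicates = 5, seed = 3)
fit_directionality(ex)
#> <directionality_fit> beta = -1.01 +/- 0.0852 -> random ( 20 assays )
```

Reading the output: the directed assay collapses 43 seeded objects into 1
(42 merges, every seed object involved — aggregating fraction 1, density
fraction 1). The growth fit recovers an area-doubling timescale τ = 3 d
and hence a cell doubling time T_d = 2τ/3 = 2 d exactly. The replicated
random-motion experiment yields a log–log slope β = −1.01 ± 0.09 across
densities 15–120 cells/mm³ — the Smoluchowski signature — and is labelled
`random`; a directed-motion experiment gives a near-flat slope and the
label `directed`.

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the
end-to-end chain (simulate → render → EDF-project → segment → filter →
count → fit → classify) is available as `run_pipeline(pipeline_config(...))`,
deterministic for a fixed seed.

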