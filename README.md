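# shrewcomp

Quantifying interspecific competition between sympatric small mammals —
a marked, generalist mouse (*Peromyscus*-type) and an unmarked,
insectivorous shrew (*Sorex*-type) — from robust-design live-trapping
records, habitat ordination scores and dual stable-isotope samples.

Field studies of competition between such "unlikely competitors" chain
several inferential stages, each with its own estimator. `shrewcomp`
implements that chain as tested, reusable R functions, together with a
synthetic-data generator that produces trapping and isotope data with known
ground truth, so every estimator can be validated by recovery experiments.

## What the package computes

**Abundance and density.** For the marked species, a closed-population
maximum-likelihood estimator within each primary session (model M0, with an
Mt variant), maximizing

    L(N, p) ∝ [N! / (N − n)!] · p^d · (1 − p)^(NT − d)

over population size N and capture probability p (n distinct individuals, d
detections, T occasions; occasions after a trap death are censored), with a
profile-likelihood 95% interval. For the unmarked species, the
dead-and-alive Horvitz–Thompson procedure: live captures are inflated by an
externally supplied detection probability and trap mortalities added back,
`N̂ = n_live / p* + n_dead`. Densities divide abundance by the effective
trapping area — the trap array's bounding rectangle plus a boundary strip
(a flat 50 m buffer, or half the mean maximum distance moved, MMDM).

**Competition coefficients.** Species densities are standardized to zero
mean and unit SD within year, and shrew density is regressed on mouse
density and habitat terms,

    Y_s = a + b_p X_p + b_1 X_1 + … + b_n X_n            (regressive)
    Y_s = a + b_s(t−1) X_s(t−1) + b_p X_p + … + b_n X_n  (auto-regressive)

where `b_p` is the competition coefficient α. All 15 regressive and 16
auto-regressive term configurations are fitted and compared by AICc, R² and
parsimony (among models with ΔAICc ≤ 2, the one with fewest parameters
wins).

**Diet mixing.** Concentration-dependent dual-isotope linear mixing:
proportions p ≥ 0, Σp = 1 satisfying, for each element e ∈ {C, N},

    δ_mix,e = Σ_i p_i · conc_i,e · δ_i,e / Σ_i p_i · conc_i,e

after adding consumer–diet discrimination (1.0‰/3.0‰ for mice, 1.3‰/2.5‰
for shrews) to the sources. With three sources the solution is unique; with
more, the feasible polytope is enumerated by vertices and summarized as
mean ± SD over uniform samples. Dietary overlap uses the >20% inclusion
criterion, and group differences are tested with a K-nearest-neighbour
randomization test.

**Isotopic niches.** Kernel utilization density surfaces in (δ¹³C, δ¹⁵N)
space, 50/75/95% probability-mass contours, areas (‰²), directed overlaps,
and a subsampling control for unequal sample sizes.

**Energetics.** Community energy consumption Σ N_i · FMR_i (field metabolic
rates mass-scaled from reference species) and year-over-year compensation
ratios — 100% is the zero-sum expectation under perfect competitive
replacement.

## Worked example

```r
library(shrewcomp)

cfg     <- sim_config(seed = 42)          # 21 grids, alpha_true = -0.9
state   <- simulate_dynamics(cfg)
records <- simulate_captures(state, cfg)

cm <- capture_matrix(records, grid = 1, year = 1, session = 1, n_occasions = 5)
m0_mle(cm)
#> Abundance estimate (m0_mle): N = 67.06 [56.62, 85.53]
```

The true abundance on that grid and session is 68, inside the profile
interval. Boundary-strip density uses the movement scale and trap geometry:

```r
mmdm(records)                        #> 30.39 m
effective_area(state$grid, 50)       #> 5.410 ha
```

Competition-coefficient recovery on a standardized session table generated
with α = −0.9:

```r
tbl <- simulate_competition_table(n_grids = 21, alpha = -0.9, seed = 1)
rk  <- fit_model_set(tbl, autoregressive = TRUE)
head(rk$table[, c("model", "k", "aicc", "delta_aicc", "r2", "alpha")], 3)
#>                                             model k     aicc delta_aicc        r2      alpha
#> 1               shrew_density_lag + mouse_density 4 22.91340   0.000000 0.8715386 -0.8737096
#> 2 shrew_density_lag + mouse_density + elevation_m 5 24.74903   1.835635 0.8738120 -0.8644103
#> 3       shrew_density_lag + mouse_density + nmds1 5 25.13389   2.220493 0.8726504 -0.8760924
rk$selected
#> "shrew_density_lag + mouse_density"
```

The parsimony rule selects the generating configuration and α̂ = −0.87 is
within sampling error of the true −0.9. Diet mixing on a shrew population
mean simulated from 30/60/10% invertebrates/earthworms/mushrooms:

```r
src <- default_sources()
iso <- simulate_isotope_data(src, c(0.30, 0.60, 0.10), noise_sd = 0.3,
                             n = 64, seed = 9,
                             offsets = c(d13c = 1.3, d15n = 2.5))
solve_mixing(c(mean(iso$d13c), mean(iso$d15n)), correct_sources(src, "shrew"))
#> diet_solution (unique)
#>   invertebrates  0.308 +/- 0.000
#>   earthworms     0.597 +/- 0.000
#>   mushrooms      0.095 +/- 0.000
```

`run_all(run_config(sim = sim_config(seed = 42)), "out/")` chains every
stage and writes `density.csv`, `competition_table.csv`, `diet_table.csv`,
`niche_table.csv`, `energy_table.csv`, `run.log` and `summary.json`;
rerunning with the same seed reproduces the bundle byte for byte.

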