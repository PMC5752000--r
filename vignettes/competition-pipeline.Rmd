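---
title: "Methods: from trap nights to energy compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from trap nights to energy compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrewcomp)
```

`shrewcomp` implements the inference chain of a two-species small-mammal
competition study: abundance and density per trapping grid and session,
standardized-regression competition coefficients with AICc model
selection, concentration-dependent stable-isotope diet mixing and
isotopic-niche geometry, and whole-community energy accounting. This
vignette documents the models, their assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## The study design being modelled

The target design is a robust-design live-trapping study: rectangular
grids of Sherman traps at 25-m spacing (40–52 traps per grid), trapped for
five consecutive nights (secondary occasions) in three primary sessions
per year over three years. One species (the mouse) is individually marked;
the other (the shrew) is released without processing, so its identity is
never known, and it suffers substantial trap mortality. Habitat enters as
two ordination axes (overstory/understory structure and food availability)
plus elevation, all per grid.

## Abundance estimation

**Marked species.** Within a primary session the population is treated as
closed and model M0 is fitted by maximum likelihood: `n` distinct
individuals, `d` total detections over `T` occasions, capture probability
profiled as `p̂ = d / E(N)` where `E(N)` is total exposure. Trap deaths are
censored: an individual that dies on occasion `t` contributes only `t`
occasions of exposure. `N` is continuous (gamma-function relaxation of the
factorial), maximized by `optimize()` on `[n, 50n]`. The 95% interval is a
profile-likelihood interval at the χ²(1) cutoff (1.92 log-likelihood
units), which remains stable at the small per-grid sample sizes where Wald
intervals collapse. When every exposure occasion produced a detection the
MLE sits on the boundary (`N̂ = n`, `p̂ = 1`); this is flagged rather than
treated as an error. With extremely sparse data the profile can plateau
and the upper bound is reported as `Inf`. A time-varying (Mt) variant is
included; at `T = 2` its estimate agrees with the Lincoln–Petersen closed
form `n₁n₂/m₂` to within the continuous relaxation (a few percent at
typical sizes), which the test suite uses as an independent oracle.

This closed-population-per-session approach deliberately replaces a full
robust-design likelihood (joint survival and abundance across primary
sessions): survival estimation is out of scope here, and within-session
abundance is all the downstream stages consume.

**Unmarked species.** Identity is unknowable, so the count of live-capture
events stands in for the minimum number known alive — a literal
convention that is biased upward when the same animal is caught on several
nights; we document rather than correct this, since any correction would
require the very detection model the data cannot support. Abundance is
then the dead-and-alive Horvitz–Thompson estimate
`N̂ = n_live / p* + n_dead`, where `p*` is an externally supplied
per-primary-session detection probability with a 95% interval. The source
literature for such borrowed probabilities does not always state whether
they are per night or per session, so `ht_abundance()` accepts either
(`per_night = TRUE` converts via `1 − (1 − p)^T`). Sessions with no
captures at all return `N̂ = 0` with a rule-of-three upper bound
`3 / p*`.

**Density.** The effective trapping area is the bounding rectangle of the
trap array expanded by a true Euclidean buffer (rounded corners):
`A + P·r + π·r²`. The default buffer is the field-standard 50 m; for the
shrew the pipeline instead uses half the mouse MMDM (the mean over
individuals of the maximum distance between consecutive captures), falling
back to 50 m when no individual was caught twice. We buffer the bounding
rectangle rather than a convex hull because the simulated (and target)
arrays are rectangular; for a rectangular lattice the two coincide.

## Competition coefficients

Density series are standardized to zero mean and unit SD per species
*within year*, pooling all grids and sessions of that year. Within-year
scope matches the per-year regressions (mouse density differs enormously
between peak and crash years, and pooling across years would let one
year's variance dominate the scale); `session_table(scope = "global")`
provides the pooled alternative. Habitat covariates are standardized
across grids as well so coefficients are comparable — this leaves the
competition coefficient α untouched, as the test suite verifies by
rescaling raw densities tenfold.

Response rows are sessions 2 and 3 of each year; the auto-regressive lag
is the same grid's previous session within the same year (no lag crosses a
winter). The candidate sets enumerate all configurations of the four
predictors — mouse density, two ordination axes, elevation — giving 15
non-empty regressive models, and the same 16 subsets (including the empty
one) with the lag term always present in the auto-regressive family.

Fits are ordinary least squares (the Gaussian identity-link GLM), with the
Gaussian maximum log-likelihood (σ̂² = RSS/n) and
`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`, where `k` counts the intercept, the
slopes and the residual variance — the convention of `logLik.lm`, and the
one implied when AICc is computed from `glm` output. Among models with
ΔAICc ≤ 2 the selected model is the one with fewest parameters, remaining
ties broken by higher R², then lower AICc. Unweighted OLS is used
throughout: weighting rows by abundance-estimate precision is defensible
but was not part of the procedure being reproduced, and the recovery tests
show the unweighted fits are well calibrated under the generator's noise.

## Diet mixing

The concentration-dependent mass balance states that a consumer's δ for
element `e` is the concentration-and-proportion weighted mean of the
(discrimination-corrected) source δs. Multiplying through by the
denominator makes both balances *linear* in the proportions, so the
feasible set is the intersection of two hyperplanes with the unit simplex:

* 3 sources: a unique solution when the corrected source triangle
  contains the mixture (solved directly; a condition number below 1e−12
  signals collinear corrected sources and raises an error);
* ≥ 4 sources: a polytope, characterized by enumerating basic feasible
  solutions over all 3-column bases (its vertices) and summarized by the
  mean ± SD of 10,000 points sampled uniformly from it. Sampling works in
  null-space coordinates: a 1-D polytope is a segment (sampled directly);
  higher dimensions use rejection from the vertex bounding box, which is
  exact uniform sampling.

Feasibility uses a mass-balance tolerance of 0.01‰ — the scale of
measurement noise — configurable in `solve_mixing()`. Every reported
solution satisfies the balance to 1e−6‰ when substituted back, and with
equal concentrations the solver reproduces the standard (non-weighted)
linear mixing solution exactly; both are tested.

The pipeline enforces the asymmetry of the field procedure: shrews are
solved on the group (population) mean because their isotopic variance is
low, mice per individual because theirs is roughly double. Dietary overlap
per source requires the shrew mean proportion to exceed 20% and reports
the percent of individual mice exceeding the same threshold.

The K-nearest-neighbour randomization test uses `k = 3` and 999 label
permutations by default (neither is dictated by the procedure being
reproduced; `k = 3` is the smallest neighbourhood robust to singletons and
999 gives a p-value resolution of 0.001). Distance ties are broken by
smallest index, deterministically. The permutation p-value
`(1 + #{perm ≥ obs}) / (n_perm + 1)` is exact-valid; with very small
groups the statistic is heavily tied and the test becomes conservative —
calibration is checked at group sizes 21 and 64, the study's low-sample
period.

## Isotopic niches

The kernel utilization density is a Gaussian-product KDE with per-axis
normal-reference bandwidths `1.06·σ·n^(−1/5)` (the default family of KUD
niche packages; a scalar multiplier is exposed). The grid is 256 × 256
cells padded 3 bandwidths beyond the data range, which captures ≥ 99.9% of
the mass on Gaussian test fixtures; the surface is renormalized so cell
masses sum to one.

A mass contour is the super-level set containing the requested probability
mass: cells sorted by density, cumulative mass, threshold at the first
cell reaching the level. Contour polygons come from marching squares
(`grDevices::contourLines`) with shoelace areas per polygon; the region's
*area* is the super-level-set area on the grid, which is what nesting and
overlap arithmetic use. Directed overlaps are computed on a common
512-cell grid spanning both regions, with membership evaluated by bilinear
interpolation of each region's own surface against its own threshold (or
point-in-polygon for synthetic polygon regions). This makes self-overlap
exactly 100%, keeps the intersection bounded by both areas by
construction, and agrees with closed-form Gaussian geometry to a few
percent (the 95% region of a standard bivariate normal has area
−2π·ln(0.05) ≈ 18.82; the KDE's bandwidth inflates this by ~σ²(1+h²), a
few percent at n = 2000, which is why the acceptance check allows 10%).

The subsampling control redraws both point sets without replacement at the
smaller period's sample sizes (5 replicates by convention), recomputes
sizes and overlaps, and reports the replicate mean with a
normal-approximation 95% CI (`mean ± 1.96·sd/√n_reps`; the convention for
the interval is not fixed by the reproduced procedure, so the CI of the
replicate mean was chosen and is stated here). Subsampling to the full
sample size reproduces the full-data values with zero-width CIs, which is
tested.

## Energetics

Community energy consumption multiplies each species' session-3 abundance
(the within-year maximum) by a per-individual field metabolic rate and
sums. The shrew FMR is mass-specific: a reference FMR at the reference
body mass 8.2 g is scaled linearly to the observed mean shrew mass per
year. The mouse FMR is used unscaled at the observed mean mouse masses
(≈ 21 g), matching the reproduced procedure; a configuration flag could
scale it too for sensitivity analysis. The reference constants themselves
(defaults: 90 kJ/day for the reference shrew, 55 kJ/day for the mouse) are
configuration values, not field measurements — the literature values used
in the original analysis are not printed there, so the defaults are
order-of-magnitude-correct placeholders whose exact values cancel in the
compensation ratios the tests assert (zero-sum replacement gives exactly
100%).

## The synthetic-data generator

`simulate_dynamics()` embeds the generative counterpart of the
auto-regressive competition model: on the standardized scale, shrew
density in sessions 2+ is `lag_coef` times the previous session plus
`alpha_true` times standardized mouse density plus habitat effects plus
Gaussian noise (`noise_sd`, default 0.3). Mouse densities are log-normal
around year-specific means with a peak (×1.6) and crash (×0.4) mimicking
an irruption cycle. Densities convert to integer abundances through each
grid's effective trapping area; negative expected densities are truncated
at zero and counted.

`simulate_captures()` places activity centres uniformly over the grid
rectangle plus a 50-m margin, perturbs them nightly by an isotropic
Gaussian (`movement_sigma = 20` m, which yields MMDM statistics of a few
tens of metres on a 25-m lattice), captures each alive individual with
per-night probability `p_night`, and records the lattice trap nearest the
perturbed position. Captures are independent across individuals and
nights; each capture is a trap mortality with probability
`mortality_prob`, after which the individual produces no further records.
Mice keep identities across sessions; shrew ids are withheld from the
output, mirroring release-without-processing. Default capture
probabilities (mice 0.25, shrews 0.10 per night) and trap mortalities
(mice 0.11, shrews 0.40) are generator choices consistent with the
qualitative contrast of the target system (low mouse, high shrew trap
mortality), not estimated values.

What the generator does **not** emulate — and what passing recovery tests
therefore do not establish about real data: trap saturation (one animal
per trap per night), heterogeneous or behaviourally varying capture
probabilities, natural mortality and recruitment within a season, true
home-range movement, spatially structured habitat, and observation error
in the habitat ordination. Estimator recovery under the generator shows
correctness of the implementations under their own assumptions, not
robustness to these violations.

Every stochastic operation draws from a child stream derived
deterministically from one master seed and a stage label, so a single
integer reproduces the entire pipeline; the end-to-end test asserts
byte-identical `summary.json` across reruns.

## Problem sizes and numerical conventions

The validation suite uses: 500 replicates for closed-population recovery
(N = 100, p = 0.3, T = 5); 200 replicates for α recovery and model-set
support (21 grids × 2 transitions, α = −0.9, noise 0.3); a 0.002-step
simplex grid (≈ 2 × 10⁷ candidate compositions) as the brute-force mixing
oracle; 2,000 draws for the Gaussian niche geometry checks; and 200 null
replicates of 999 permutations for KNN calibration. These sizes give
Monte-Carlo error comfortably below the assertion margins while keeping
the full suite around a minute.

Degenerate inputs are rejected loudly rather than patched: zero-variance
standardization names the offending series, collinear designs name the
collinear term, collinear corrected sources raise an ill-conditioned
error, sub-10-point niche fits are refused, and zero reference energy
yields an undefined compensation marker.

## Known limitations

* The live-capture-event MNKA convention for unmarked animals
  double-counts within-session recaptures; shrew abundances inherit this
  upward bias (and the borrowed `p*` its external validity).
* The M0 estimator ignores individual heterogeneity; with trap-happy or
  trap-shy animals it is biased like any M0 fit.
* Niche areas are grid-resolution-limited (refinement from 200 to 400
  cells moves Gaussian-fixture areas by < 2%, tested) and
  bandwidth-inflated relative to the underlying distribution.
* The polytope mean ± SD summarizes the feasible set, not a posterior:
  it weights all mass-balance-consistent diets equally.
* Compensation ratios compare point estimates; interval propagation
  through the energy budget is by endpoint arithmetic only if requested
  and is not a substitute for a joint error model.
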