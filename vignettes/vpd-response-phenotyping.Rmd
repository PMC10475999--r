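---
title: "Phenotyping transpiration responses to vapour pressure deficit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping transpiration responses to vapour pressure deficit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpdresponse)
```

## The experiment this package analyses

A step-change drying experiment on well-watered plants: air vapour pressure
deficit (VPD) is raised in discrete steps by lowering relative humidity at
constant temperature, while (a) a gas analyser logs leaf-level stomatal
conductance `gs`, transpiration `E` and photosynthesis `A` about once per
minute, and (b) a precision balance logs whole-plant mass every ~10 s.
Each plant experiences six leaf-VPD levels (≈0.91, 1.50, 2.09, 2.69, 3.28,
3.87 kPa) or five chamber-VPD levels (≈0.77, 1.36, 1.93, 2.34, 2.64 kPa),
the first held 90 min and the rest 60 min. The biological question is how
strongly, and from which VPD onwards, a genotype restricts transpiration as
evaporative demand rises — a trait relevant to drought-tolerance breeding.

Set-point and realized VPDs are kept as distinct fields throughout: chamber
control overshoots and instrument drying capacity make the realized step
means differ from the set-point computation, so the two are never asserted
equal. Records are assigned to steps by elapsed time, not by matching RH
readings, because RH overshoots during transitions make value-matching
ambiguous.

## Vapour-pressure physics

Saturation vapour pressure uses the Tetens formula
`es(T) = 0.6108 exp(17.27 T / (T + 237.3))` (kPa, T in °C, valid here for
0–60 °C) and `VPD = es(T)(1 − RH)`. Tetens, Magnus and Buck agree to within
about 0.1 % over this range and all reproduce the protocol's first chamber
step (36 °C, 87 % RH → 0.77 kPa) to two decimals; the constants are fixed
so every derived quantity is reproducible. Relative humidity is a fraction
everywhere inside the package; readers convert percent at the boundary
once, which avoids double-conversion bugs. Leaf-to-air VPD is the same
computation applied with leaf temperature; leaf temperature is taken as
measured, never modelled (no leaf energy balance).

## Steady-state extraction

The protocol holds each level long enough that gas exchange equilibrates;
the per-level "steady state" is operationalized as the mean over the final
`window_min` minutes (default 5) of the step, rather than the last
instantaneous reading, because single records are noise-sensitive. The
window length is configurable; for constant signals the estimate is
invariant to sampling density. Levels without records in the window are
flagged missing and never fabricated; downstream statistics use available
levels only. Intrinsic water use efficiency is recomputed per row as
`iWUE = A/gs` (µmol CO₂ mol⁻¹ H₂O), undefined for a closed stoma.

## Leaf-level response statistics

**Transpiration reduction (ϕ_E).** For each plant the exact line through
`(VPD, E)` at the two lowest levels (a regression through two points *is*
that line; equal-VPD baselines are rejected as degenerate) is extrapolated
to each high-VPD level, and `ϕ_E = 1 − E_meas / E_pred`. Zero means the
response stayed linear; negative values (super-linear response) are legal
and preserved. Extrapolations with non-positive `E_pred` are flagged
invalid rather than dropped silently. ϕ_E is invariant to rescaling all
rates, so it compares instruments and scales. Plants missing a baseline
level are excluded with a logged reason. Aggregation to accession is the
mean ± standard error over plants.

**Limitation of A.** Per accession and level,
`sum(A_max − A_meas) / sum(A_meas)`, where `A_max` is each plant's maximum
steady-state A across levels and the sums run over the accession's plants
at that fixed level. The per-level (not cumulative) reading is used because
the statistic is reported as level-specific values. It is non-negative and
zero exactly when every plant sits at its own maximum.

**Stomatal reduction (ϕ_stom).** Ordinary least squares of `gs` on
`log(VPD_leaf)` per plant: `gs = a − ϕ_stom log(VPD_leaf)`, with `a` the
fitted conductance at 1 kPa and ϕ_stom reported as the absolute slope. The
fit is per plant and averaged to accession afterwards, which matches
per-plant error bars; at least three levels are required per plant.

## Gravimetric whole-plant transpiration

Mass is averaged over the first and last 5 minutes of each chamber step and
differenced: `E_rate = (m̄_start − m̄_end) / (LA · Δt)`, with Δt the time
between window centres, converted to mmol m⁻² s⁻¹ by the molar mass of
water (18.015 g mol⁻¹). Start-minus-end is a deliberate sign choice so that
a transpiring plant has a positive rate (the end-minus-start difference of
a falling mass trace is negative). Pot evaporation is assumed zero because
the soil surface is covered; mass gains beyond a configurable tolerance
trigger a watering-event warning instead of a silent negative rate. The
whole-plant ϕ_E uses the identical two-point contract with the two lowest
chamber steps as baseline and the highest step as target.

## Segmented regression and the Davies test

The transpiration response to VPD is modelled as a broken stick with a
shared breakpoint per accession and fixed per-plant intercepts:

y = α_plant + β₁ x + β₂ (x − ψ)₊ + ε.

Random plant intercepts would match the experiment's nesting, but with 3–8
plants per accession variance-component estimation is fragile; fixed
dummy-coded offsets leave the estimands (ψ and the slopes) unchanged and
are used instead — a documented approximation, not an oversight.

**Estimation.** At a working ψ the model is linearized with regressors
`U = (x − ψ)₊` and `V = −1{x > ψ}`; `V`'s coefficient γ estimates
`β₂(ψ_true − ψ)`, so ψ is updated by `γ̂/β̂₂` until the update falls below
1e-6 kPa (at most 50 iterations), with ψ constrained to the interior of the
observed range (one smallest-gap away from either extreme). This update is
not a descent step and the RSS profile on noisy small samples can be
multimodal, so two safeguards run by default: the linearization is started
from the midpoint of every interval between consecutive distinct `x`
values, and each such interval is additionally searched by bounded
golden-section minimization of the profile RSS. The best-RSS solution is
kept. On noiseless piecewise-linear input the fit is exact (zero RSS), and
the fitted mean function is continuous at ψ by construction.

**Uncertainty and flags.** `SE(ψ) = SE(γ̂)/|β̂₂|` (delta method) at the
solution; slope standard errors come from the refit without `V`. When
`β̂₂ ≈ 0` the breakpoint location is meaningless and the fit is flagged
`no_slope_change` with an undefined SE. With a handful of discrete VPD
levels the RSS can be exactly flat between two adjacent observed values —
ψ is then only interval-identified; the fit reports the interval midpoint
and flags `interval_identified`. This is also why printed breakpoints from
any specific experiment should be read as interval statements. Solutions
pinned at the search boundary are flagged `boundary`.

**Davies test.** Under the linear null the breakpoint does not exist, so a
standard likelihood ratio is unavailable. The Wald t statistic for β₂ is
computed at K = 10 candidate breakpoints equally spaced between the 2nd and
(n−1)th ordered distinct `x` (K shrinks with a warning when fewer distinct
values exist). With `M = max |t|` and `V` the total variation of `|t|` over
the grid, the reported p-value is the two-sided Davies upper bound

p = min(1, 2 [Φ(−M) + V exp(−M²/2) / √(8π)]).

The doubling is the union bound for a two-sided alternative; without it the
one-sided bound applied to `|t|` is anti-conservative (measured null
rejection ≈ 0.10 at α = 0.05 in this package's calibration simulations,
versus ≈ 0.06 with the doubling — the bound is by nature slightly
conservative). The exact variant of the test (score vs Wald statistic, grid
size and placement) differs between implementations and versions; the
choices here are fixed and documented rather than inherited as hidden
defaults. Perfect fits (zero residuals at a candidate) are handled
explicitly: no slope change means zero evidence, a genuine slope change
means overwhelming evidence.

## Cohort analysis

Sixteen accession-level traits feed clustering: limitation of A at leaf
levels 2–6, ϕ_E at the three highest leaf levels and the top whole-plant
step, breakpoint, slope before and slope after at both measurement levels,
and ϕ_stom. Accession means are z-scored per column; a constant column is
an error (it carries no information and breaks scaling), and accessions
missing a trait are dropped with a logged reason (mean imputation is
available but off by default).

k-means uses Lloyd iterations from 10,000 random centre sets (k distinct
data rows each); restarts that collapse to an empty cluster are discarded
and counted, and the minimal within-cluster sum of squares solution is
kept, deterministically for a given seed. k = 3 is a configured input: a
mean-silhouette-versus-k diagnostic is emitted so the choice can be
inspected, but nothing auto-selects k. PCA is computed on the same scaled
matrix used for clustering; loadings are unit-norm eigenvectors reported
for the first two components, ordered by |PC1| loading, with each
component's sign fixed so its largest-magnitude loading is positive
(PCA signs are otherwise arbitrary, and reproducible tables matter more
than any particular orientation).

Accession differences in the per-level steady-state values are tested by
one-way ANOVA per level, with Benjamini–Hochberg correction applied across
the per-level family within one measurement type. Trait–trait association
is the squared Pearson correlation with its two-sided t-test.

## The synthetic cohort generator

No instrument data ship with the package; a generator produces full
cohorts with known ground truth so that every stage is testable. Its
defaults encode the study conditions: three archetype groups of 1, 2 and 6
accessions, five plants each, the six leaf and five chamber VPD levels
above, 90/60-min steps, 60-s gas-exchange and 10-s balance sampling.

Per plant: `gs(V) = a − ϕ_stom log V` (floored at a small positive value),
transpiration piecewise-linear in V with the group's breakpoint and slopes
plus a Gaussian per-plant intercept, and photosynthesis coupled to
conductance by a rectangular hyperbola `A = A_max gs/(gs + g50)` — one
interpretable parameter that makes A-limitation grow with stomatal closure
(with `g50 = 0.05 mol m⁻² s⁻¹` the top-level limitation lands in the
realistic 7–20 % range). The archetypes encode the qualitative contrasts of
the three phenotypic groups: I breaks early with a low slope before the
break; II breaks around 2 kPa with a negative slope after it at both
measurement levels; III breaks late and keeps a high positive slope. The
slope change is always a reduction. Within a step, signals approach their
steady value exponentially with a 10-min default time constant, so
end-of-step windows are effectively steady; the fast (~20 min) hormonal
kinetics of stomatal closure are deliberately not modelled. The balance
trace integrates transpiration times leaf area with the molar-mass
conversion, so mass is conserved exactly before reading noise is added.
Observation noise defaults (gs 0.01 mol m⁻² s⁻¹, E 0.05 mmol m⁻² s⁻¹,
A 0.3 µmol m⁻² s⁻¹, balance 0.02 g at 0.01 g resolution) reflect
instrument-scale scatter; between-plant intercept SDs (0.15 leaf,
0.05 whole-plant) reflect biological replication.

One master seed drives everything; per-plant streams are derived by stable
hashing of (accession, plant), so adding a plant never perturbs any other
plant's draws and regeneration is byte-identical.

**What passing tests on synthetic cohorts do and do not show.** The
generator produces exactly the model family the estimators assume:
piecewise-linear responses, Gaussian noise, log-linear conductance, steady
steps. Recovery there demonstrates correctness of the computations, not
robustness to real-data pathologies — drifting baselines, watering events,
non-Gaussian instrument glitches, leaf growth during the run, or genotypes
with no breakpoint at all. The missing-level flags, watering-event warning
and `no_slope_change`/`boundary` flags are the package's handles on those,
but they are not exercised by realistic failure data.

## Simulation study sizes and numerical choices

The package's own validation simulations use: 50 random instances (12–40
points) for equivalence of the iterative fit with an exhaustive
2000-candidate profile of the RSS; 200 simulated accessions at the
experimental design (6 levels × 5 plants, breakpoint 2.0 kPa, slopes
2.5 → 0.5, intercept SD 0.3) with observation noise SD 0.15 — about 10 % of
a whole-plant-scale mean transpiration rate — for estimator recovery; 500
linear-null replicates (σ = 0.2) for the Davies test's size; and 500
replicates per effect size for its power monotonicity. These sizes keep the
full suite to a few minutes while leaving Monte-Carlo error well below the
margins being checked.

Other numerical choices: ψ convergence tolerance 1e-6 kPa; golden-section
tolerance 1e-8; flat-profile detection at relative 1e-10; `β̂₂ ≈ 0`
threshold 1e-8 relative to the slope scale; BH family = per-level tests of
one measurement type; k-means `iter.max` 100. Ties in k-means restarts
resolve to the first minimal within-SS solution under the fixed seed.

## Known limitations

- One breakpoint only; no multi-phase or Bayesian changepoint inference.
- Fixed, not random, plant intercepts (see above); no random slopes.
- Breakpoints are interval-identified with few discrete VPD levels; treat
  ψ comparisons across genotypes accordingly.
- The Davies bound is conservative; with very few distinct levels the
  candidate grid collapses and power drops.
- Leaf area is an input number (destructive imaging happens outside the
  pipeline); no growth correction over the measurement day.
- The generator does not emulate diurnal cycles, water-deficit treatments,
  ABA kinetics or hydraulic mechanisms — it is a test harness for the
  statistics, not a physiological simulator.
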