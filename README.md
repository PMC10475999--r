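# vpdresponse

Phenotyping pipeline for transpiration responses to rising vapour pressure
deficit (VPD), built for step-change drying experiments on well-watered
plants: leaf gas-exchange time series (stomatal conductance `gs`,
transpiration `E`, photosynthesis `A` logged ~every 60 s across six
leaf-VPD levels) and gravimetric whole-plant balance logs (~every 10 s
across five chamber-VPD levels). The intended users are plant
ecophysiologists and breeders screening genotypes — e.g. gene-bank
accessions of crop wild relatives — for water-saving stomatal behaviour
under high evaporative demand.

## What it computes

From raw series the pipeline derives, per plant and VPD level, steady-state
`gs`, `E`, `A` and intrinsic water use efficiency `iWUE = A/gs`, and from
those the response statistics of the field:

- **Transpiration reduction** `ϕ_E = 1 − E_meas / E_pred`, with `E_pred`
  the extrapolation of the line through the two lowest-VPD levels — the
  fractional shortfall of transpiration below its linear expectation.
- **Limitation of A** `= Σ(A_max − A_meas) / Σ A_meas` per accession and
  level, with `A_max` each plant's maximum across levels.
- **Stomatal reduction** `ϕ_stom`: the absolute slope of
  `gs = a − ϕ_stom·log(VPD_leaf)`, with `a` the conductance at 1 kPa.
- **Whole-plant transpiration rate**
  `E_rate = (m̄_start − m̄_end) / (LA·Δt)` from 5-min balance mass windows,
  normalized by leaf area `LA` and converted to mmol m⁻² s⁻¹.
- **Segmented (broken-stick) regression** of `E` on VPD,
  `y = α_plant + β₁x + β₂(x − ψ)₊`, with per-plant intercepts, an estimated
  breakpoint `ψ` (delta-method SE) and the **Davies test** of the segmented
  response against the linear null — the breakpoint exists only under the
  alternative, so the test maximizes a Wald statistic over candidate
  breakpoints and applies the Davies upper bound.
- **Phenotypic grouping**: a 16-trait accession matrix (z-scored), k-means
  over 10,000 random centre sets, PCA projection with a |PC1|-ordered
  loadings table, per-level ANOVA with Benjamini–Hochberg correction, and
  trait–trait R².

Because raw instrument data are rarely deposited, the package ships a
synthetic-cohort generator (`generate_cohort()`) with a ground-truth
manifest: three response archetypes (conservative early limiter; high-flux
shutdown with negative post-breakpoint slope; risk-taking sustained
transpiration) emitted as the exact CSV dialects the readers consume, so
every stage is testable end to end.

## Worked example

```r
library(vpdresponse)

# chamber VPD at 36 degC for the protocol's RH steps
round(vpd(36, c(0.87, 0.78, 0.68, 0.62, 0.56)), 2)
#> [1] 0.77 1.31 1.90 2.26 2.61

# one accession: 5 plants, 6 leaf-VPD levels, true breakpoint at 2 kPa
d <- simulate_accession_response(n_plants = 5, psi = 2.0, slope_before = 2.5,
                                 slope_after = 0.5, intercept_sd = 0.3,
                                 noise_sd = 0.15, seed = 42)
fit <- fit_segmented(d$vpd, d$E, plant = d$plant)
fit
#> Segmented regression fit
#>   breakpoint psi: 2.0173 kPa (SE 0.0943)
#>   slope before:   2.4966 (SE 0.0995)
#>   slope after:    0.4789 (SE 0.0590)
#>   n = 30, plants = 5, RSS = 0.784785, converged = TRUE (3 iter)

davies_test(d$vpd, d$E, plant = d$plant)
#> Davies test: max |t| = 13.979 over 4 candidate breakpoints, p = 2.857e-42
```

The fitted breakpoint (2.02 kPa) and slopes (2.50 → 0.48) recover the
generating values (2.0, 2.5 → 0.5) within their standard errors, and the
Davies p-value rejects a linear response decisively.

## The analysis workflow

`analysis/` holds the numbered pipeline; each stage is a thin driver over
the package functions, reports what it found, and writes tables under
`results/` (raw simulated traces go under `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R      # 9-accession synthetic cohort
Rscript analysis/02_steady_state.R         # per-plant x level steady states
Rscript analysis/03_leaf_metrics.R         # phi_E, A limitation, phi_stom
Rscript analysis/04_whole_plant.R          # gravimetric rates, phi_E
Rscript analysis/05_segmented_fits.R       # breakpoints, slopes, Davies p
Rscript analysis/06_cohort_analysis.R      # traits, k-means, PCA, ANOVA
Rscript analysis/07_ground_truth_validation.R
```

On the default cohort this reports leaf breakpoints of 1.76–2.63 kPa (all
Davies p < 0.05), top-level ϕ_E of 0.10–0.52, A limitation of 7.6–19.5 %,
negative post-breakpoint slopes for the shutdown archetypes, a silhouette
diagnostic peaking at k = 3, and full recovery of the planted partition
(adjusted Rand index 1.000; 64/64 ground-truth checks pass).

See `vignettes/vpd-response-phenotyping.Rmd` for the models, assumptions,
parameter defaults and numerical choices.

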