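# pillscaling

Urban-scaling analysis of opioid analgesic (oxycodone/hydrocodone) pill
distribution across US commuting zones.

## The problem

Opioid prescribing in the US varied enormously across places during the
2006–2014 run-up of the overdose crisis. The urban-scaling framework asks
how an aggregate outcome Y of a spatial unit grows with its population N:

    ln(Y_i) = α + β · ln(N_i) + ε_i

β is the scaling exponent — the elasticity of the outcome with respect to
population. β > 1 is *superlinear* (disproportionately more in larger
units), β < 1 *sublinear*, β = 1 linear (proportional). For pill counts
across commuting zones (CZs — clusters of counties grouped by commuting
flows, covering the whole continental US), a single exponent is
misspecified: residuals form a U against log-population. The package
therefore fits a *continuous two-regime* power law via a linear spline in
ln N with a single knot k:

    ln(Y_i) = α + β₁ ln(N_i) + (β₂ − β₁)(ln N_i − ln k)·1[N_i > k] + ε_i

β₁ governs units below the knot, β₂ above it; the mean is continuous at
ln k by construction. The knot is chosen by exhaustive profile likelihood
over observed populations (between the 5th and 95th population
percentiles), and the spline's improvement over the single-exponent model
is judged by AIC. Regimes are classified from 95% confidence intervals:
superlinear iff the lower bound exceeds 1, sublinear iff the upper bound
is below 1.

The package implements the full pipeline for epidemiologists and
quantitative geographers working with county-level surveillance counts:

- **Aggregation** — county pills + populations + a county→CZ (or CBSA)
  crosswalk → unit table, with exclusion of units touching non-contiguous
  states, census-region assignment by population majority, and hard
  errors (never imputation) on unmapped counties or missing
  population-years.
- **Scaling fits** — single- and two-regime OLS on the log-log scale,
  covariate adjustment (e.g. region dummies), stratified fits, knot
  search, AIC comparison, regime classification.
- **Diagnostics** — residuals, standardized-residual outlier flagging,
  loess smoother against log-population, outlier-exclusion sensitivity
  refits (fixed knot or re-searched), GeoJSON export for mapping.
- **Synthetic data** — a seeded generator with stored ground truth
  (heavy-tailed populations, two-regime outcomes, log-normal noise,
  county disaggregation) so every estimator is validated by parameter
  recovery.

## Worked example

```r
library(pillscaling)

cfg <- synthetic_config(n_units = 300, sigma_noise = 0.3, seed = 2026)
d   <- generate_units(cfg)          # truth: beta1 1.36, beta2 0.92, knot 82,363
ll  <- log_log_data(d$units)

ks <- search_knot(ll)               # exhaustive profile-likelihood search
print(ks$fit)
#> Two-regime scaling fit (n = 300; knot = 68,157.55; 89 below / 211 above)
#>   beta1 = 1.422  [1.344, 1.499]
#>   beta2 = 0.931  [0.908, 0.954]
#>   alpha = 4.379  sigma = 0.294  AIC = 122.2

cmp <- compare_aic(ks$fit, fit_power_law(ll))
#> AIC: two-regime 122.2 vs single-regime 213.0  -> spline strongly preferred

classify_regime(ks$fit$beta1, ks$fit$beta1_ci)$regime   # "superlinear"
classify_regime(ks$fit$beta2, ks$fit$beta2_ci)$regime   # "sublinear"
```

Both true exponents are covered by their intervals, the dual
superlinear/sublinear pattern is detected, and the selected knot (68,158,
the 29.5th population percentile) sits near the true 82,363 — knot
localization is the least precise part of the estimator (see the methods
vignette).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on simulated data
and leave their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # 607 units at study-scale truth -> county CSVs
Rscript analysis/02_aggregate.R     # counties -> units, regions, mass audit
Rscript analysis/03_fit_scaling.R   # fits, knot search, AIC, stratified table
Rscript analysis/04_residuals.R     # residuals, smoother, GeoJSON, sensitivity
```

Each stage prints what it found and writes machine-readable fit JSONs,
the knot-search profile, residual CSVs and a GeoJSON residual map.

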