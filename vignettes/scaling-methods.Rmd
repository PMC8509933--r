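---
title: "Two-regime urban scaling of pill distribution: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-regime urban scaling of pill distribution: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillscaling)
```

## The model

Urban scaling treats an aggregate outcome $Y_i$ of spatial unit $i$ as a
power law of its population $N_i$, estimated on the log-log scale by OLS:

$$\ln Y_i = \alpha + \beta \ln N_i + \varepsilon_i, \qquad
\varepsilon_i \sim \mathcal N(0, \sigma^2).$$

The exponent $\beta$ is an elasticity: a unit 1% larger in population has
$\beta$% more of the outcome. $\beta > 1$ is superlinear, $\beta < 1$
sublinear. For opioid pill counts across commuting zones a single
exponent is inadequate — the residuals trace a U in log-population — so
the core model is a continuous single-knot linear spline in $\ln N$:

$$\ln Y_i = \alpha + \beta_1 \ln N_i +
(\beta_2 - \beta_1)\,(\ln N_i - \ln k)\,\mathbf 1[N_i > k] +
\varepsilon_i.$$

$\beta_1$ is the exponent below the knot population $k$, $\beta_2$ above
it. The hinge regressor makes the mean continuous at $\ln k$ whatever the
coefficients; $\beta_2$ is the sum of the $\ln N$ coefficient and the
hinge coefficient $\gamma$, and its 95% interval uses
$\operatorname{Var}(\hat\beta_1 + \hat\gamma)$ from the coefficient
covariance matrix with $t_{n-p}$ quantiles. Units whose population equals
$k$ exactly sit on the below-knot side (the hinge uses the strict
inequality $N > k$).

All logs are natural. The exponents are invariant to the log base and to
rescaling $Y$ (multiplying all counts by $c$ only shifts $\alpha$ by
$\ln c$ — a property the test suite checks exactly), but $\alpha$, the
log-likelihood and AIC are not, so reported values assume natural logs.

## Knot selection and model comparison

The knot is estimated by exhaustive profile likelihood: every observed
unit population strictly between the 5th and 95th population percentiles
is a candidate; for each, the spline model is fit by OLS and the Gaussian
log-likelihood recorded; the candidate minimizing the residual sum of
squares (equivalently maximizing the likelihood) wins, ties going to the
smallest candidate. At a few hundred units this costs a few hundred small
least-squares solves — exact, deterministic, and free of the convergence
and starting-value ambiguities of iterative breakpoint estimators. The
full profile is returned so flat regions around the optimum are visible.

Spline versus line is judged by AIC with the full Gaussian log-likelihood
(constants included) and the residual SD counted as a parameter:
$\mathrm{AIC} = -2\ell + 2p$ with $p = 3$ for the line
($\alpha, \beta, \sigma$) and $p = 4$ for the spline — the convention
`stats::AIC` applies to an `lm`. Because the spline nests the line, its
RSS can never exceed the line's (another exact test), and AIC asks
whether the improvement is worth one extra parameter.

Two choices here are interpretations worth stating. First, the knot
criterion is *maximum* likelihood (minimum negative log-likelihood);
describing breakpoint selection as "minimizing the log likelihood" is a
common shorthand for the same thing, and under Gaussian errors both
reduce to minimizing RSS. Second, the reported intervals condition on the
selected knot: selection uncertainty is not propagated, which
anti-conservatively narrows the exponent CIs when the profile is flat.
This matches standard practice for segmented fits but is a known
limitation.

Regimes are classified from the 95% interval, not the point estimate:
superlinear iff the lower bound exceeds 1, sublinear iff the upper bound
is below 1, linear otherwise. An interval touching 1 is linear.

## Aggregation and regions

County records enter as three CSVs (pills by county-year, population by
county-year, county→unit crosswalk). Unit totals sum pills over the
window (default 2006–2014); the unit population $N_i$ is the mean over
years of the within-year county sum. Units containing any county in an
excluded state (default the non-contiguous AK and HI) are dropped whole,
and the dropped pill mass is retained in an audit attribute so
conservation can be asserted. A county in the pill data but absent from
the crosswalk, or any retained county missing a population year, is a
hard error listing the offenders — silent imputation would contaminate
the fit invisibly.

Census-region assignment for a unit spanning states in different regions
is not defined by any authority; the package's rule is
population-majority (sum mean population by region within the unit, take
the largest; an exact tie goes to the alphabetically first region, with a
warning). It is deterministic and weights by the quantity the model
actually uses. Units with zero pills cannot enter a log-log fit and are
dropped by `log_log_data()` with a warning naming them.

## Residual diagnostics and sensitivity

Residuals are observed minus fitted on the log scale; standardized
residuals divide by the fit's degrees-of-freedom-corrected $\hat\sigma$,
so on well-specified data their spread is close to 1 (checked within 5%
at $n = 400$). "Strong outlier" has no canonical definition; the default
rule flags $|z| \ge 3$ with the sign reported separately, and the
threshold is a parameter. The loess smoother of standardized residuals on
$\ln N$ (span 0.75 by default — the conventional local-regression
default; quadratic local fits; evaluated on a 101-point even grid) is the
diagnostic that reveals the U shape motivating the spline.

The sensitivity pair mirrors how influential negative outliers are
handled: refit excluding them with the knot held fixed, and refit with
the knot re-searched on the reduced data (reporting the new knot and its
population percentile). With an empty exclusion set and a fixed knot the
refit is identical to the original — an exact no-op test.

Residuals export as an RFC 7946 GeoJSON FeatureCollection keyed by
`unit_id` for joining to commuting-zone boundary polygons; the package
ships no cartography and the analysis scripts demonstrate the export with
synthetic square polygons.

## The synthetic generator

`generate_units()` inverts the analysis model: ln-populations are drawn
log-uniform on $[\ln 10^4, \ln 2\times 10^7]$ (the commuting-zone range),
$\ln Y$ follows the continuous two-regime mean plus
$\mathcal N(0, \sigma_{\text{noise}}^2)$ noise, and $Y$ is rounded to a
positive integer because pill totals are counts (at realistic magnitudes
the rounding perturbs $\ln Y$ by under $10^{-7}$, and the noiseless
configuration is recovered to that precision). Defaults are the
study-scale conditions: 607 units, intercept 5, exponents 1.36/0.92,
knot 82,363, noise SD 0.4 — the noise level that reproduces the visual
scatter of the observed log-log cloud — and region weights proportional
to the study's regional unit counts (202/38/248/119). The population law
is log-uniform by default because the true CZ size distribution is not
part of the model; it gives even leverage on both sides of the knot.
Log-normal and truncated-Pareto (Zipf-like) alternatives are provided for
realism studies, both drawn by inverse CDF on the same support.

`disaggregate_to_counties()` splits each unit into counties (symmetric
Dirichlet population shares; pills allocated proportionally to population
shares and uniformly over years, with the floor of the expected cell
count allocated deterministically and only the small remainder drawn
multinomially so unit totals are conserved *exactly* even when they
exceed integer range). Aggregating the result reproduces the unit table —
pills exactly, populations within county rounding — which is the
conservation property the tests assert end to end.
`inject_outliers()` plants signed displacements of a chosen magnitude (in
units of $\sigma_{\text{noise}}$) on random units and records their ids
in the stored truth for plant-and-recover tests.

Everything is bit-reproducible under (config, seed). What the generator
does *not* emulate: spatial autocorrelation between neighboring units,
temporal dynamics within the window, heteroskedastic or heavy-tailed
noise, and any dependence of county counts on anything but population
share. Passing recovery tests therefore validates the estimators under
the model's own assumptions, not the model's adequacy for real
surveillance data.

## Validation results the suite computes

- **Oracle equivalence.** On every fixture of $n \le 20$, all
  coefficients, $\sigma$, log-likelihoods and CIs match an independent
  normal-equations solver (explicit $(X'X)^{-1}X'y$ on the hand-built
  hinge basis) to $10^{-8}$ relative tolerance, and the knot search
  matches a literal argmin-of-RSS enumeration.
- **Recovery.** Over 500 replicates at the study-scale default
  configuration, the mean fixed-knot estimates of $\beta_1$ and
  $\beta_2$ land within 0.02 of truth, and both 95% CIs cover the truth
  at 95% ± 3 percentage points.
- **Knot localization** is the noise-limited step: with noise SD 0.2 the
  searched knot falls within ±15% (0.15 in $\ln k$) of the truth in well
  over 80% of replicates and its median is on target; at noise SD 0.4
  the median remains on target but the per-replicate rate drops to
  roughly 60% — the profile is flat near the optimum, so individual
  selected knots scatter widely even when the exponents are
  well-estimated. Single runs should always be read alongside the
  returned profile.
- **Outlier handling.** Planted $-5\sigma$ outliers are recovered exactly
  by the default flagging rule at moderate sample sizes; at $n = 607$,
  chance $|z| \ge 3$ exceedances (about 1.6 expected under Gaussian
  noise) begin to accompany them. Excluding planted outliers lowers the
  mean exponent error across replicates, though with only three mild
  contaminants the improvement in any single replicate is small relative
  to sampling noise.

Problem sizes in the default suite (500-replicate recovery and coverage
sets at $n = 607$; 200-replicate exclusion experiments at $n = 300$;
fixtures of 5–60 points for exact checks) were chosen so Monte-Carlo
error is comfortably below every asserted tolerance while the whole
suite runs in well under a minute.

## Known limitations

- One knot only: the model cannot express more than two regimes, and no
  multi-knot or smooth (e.g. spline-basis) alternative is fit.
- Fixed-knot inference after data-driven selection (discussed above).
- Homoskedastic Gaussian errors; no robust or bootstrap inference.
- The exhaustive search is quadratic-ish in $n$ (one small solve per
  candidate); at a few thousand units it is still sub-second, but for
  much larger problems a coarsened candidate grid (the `candidates`
  argument) is the intended control.
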