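---
title: "Estimating flowering-phenology responsiveness from herbarium specimens: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating flowering-phenology responsiveness from herbarium specimens: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoherb)
```

## The problem

Direct long-term observations of flowering are rare, but herbaria hold dated,
georeferenced specimens spanning a century or more. A specimen caught at peak
flowering (more than half of its flower buds in anthesis) timestamps that
phenophase for its collection year and place. Pairing each specimen with the
temperature its plant experienced — the monthly mean of its NOAA climate
division, averaged over a window of months ending at flowering — turns a
specimen archive into a regression design spanning years and divisions.

## Models

**Division temperatures.** For month *m*, division *j*, year *k*, the
division mean is the unweighted average of the reporting stations in that
division. Stations with gaps simply drop out of the affected months (the
per-month station count is retained); nothing is imputed, and a missing
month inside a requested window is an error rather than a silent fill.
Statewide series average the division means, not the stations, so a
station-dense division does not dominate the state signal.

**Seasonal trends.** Yearly season means (default February–May, "spring")
minus their full-record average give anomalies; an OLS fit of anomaly on
year gives the warming slope, its two-sided t-test, and the total change
(slope × span). Anomaly subtraction moves only the intercept, so the trend
equals the trend of the raw seasonal means — one of the package's invariant
tests.

**Responsiveness.** Per species, flowering day-of-year is regressed by OLS
on the windowed mean temperature, each specimen paired with its own year and
division. The slope ρ (days °C⁻¹) is the quantity of interest; its OLS
standard error and two-sided t-test drive the significance classes
(significant-negative / significant-positive / nonsignificant at α = 0.05,
uncorrected across species — an optional Benjamini–Hochberg adjustment is
off by default). At least 10 specimens are required, and records collapsing
to a single temperature value are an error (the slope would be undefined).

**Group comparisons.** Differences among functional groups (flowering
season, growth form, pollination syndrome, origin) are modelled at the
specimen level: `doy ~ temp * group` with species-level random intercepts
and random temperature slopes (unstructured 2×2 covariance; on a singular
fit the model falls back to independent effects and the result is flagged).
Reported effects come from REML; significance from likelihood-ratio tests
after maximum-likelihood refits, with degrees of freedom counted as the
difference in fixed-effect parameters. Per-group contrasts against the
reference level are single-df LR tests built by collapsing that group's
slope level into the reference's (with only two groups this contrast *is*
the interaction test). Temperature is centred before fitting; slopes are
unaffected. A robustness variant adds division-level random intercepts and
slopes and reports how the group slopes move; because the null for the extra
variance components sits on the parameter-space boundary, its chi-squared
p-value is conservative.

**Phylogenetic signal.** Species-level ρ values are modelled as an
intercept-only GLS with residual covariance σ²·V(λ), where V is the
Brownian shared-path covariance of the tree and V(λ) multiplies the
off-diagonal entries by λ (Pagel's transform). For each λ on a grid over
[0, 1] (step 0.001) the Brownian rate σ² is profiled out analytically and
the multivariate-normal log-likelihood recorded; the ML λ is the grid argmax
with a local quadratic refinement, and the 95% interval collects grid points
within ½·χ²₁(0.95) of the maximum. Estimating σ² afresh at each λ is the
standard treatment when the rate is a free parameter.

## Numerical choices

* For ultrametric trees (constant V diagonal) the profile uses one
  eigendecomposition of V, making each grid point O(n); other trees use a
  Cholesky factorisation per grid point. Both routes agree with a dense
  multivariate-normal oracle to 10⁻⁸ in the tests.
* Zero-length terminal branches are perturbed by 10⁻⁸ × tree depth (with a
  message) so the covariance stays nonsingular; a star-like (flat) profile
  is reported as unidentifiable rather than returning an arbitrary argmax.
* Window means wrap cleanly across the calendar year (a February ending,
  4-month window reaches back to the prior November).
* Deduplication keys on species + date + location + collector, where
  location is the free-text locality when present and the division code
  otherwise; the first record in input order is kept.
* A species' reference flowering month is the modal calendar month of its
  retained specimens, ties broken toward the earlier month.

## Window policy

The default analysis window is 4 months ending at each specimen's own
flowering month — except species whose reference month is April, which get
the fixed February–April window (January temperatures carry little signal
for April flowering). Two further policies are exposed:

* `empirical_max`: per-species argmax of |Pearson correlation| over window
  lengths 1–12. Adjacent lengths share most of their months (the w = 3 and
  w = 4 covariates correlate at ≈ 0.87 under independent monthly
  anomalies), so single-species selection is noisy at herbarium sample
  sizes; it is provided for exploration, and `select_window_cohort()`
  pools the screen across species — the argmax of the *mean* absolute
  correlation — which is how a single averaging period is settled for a
  whole study. At the 141-species study scale the cohort screen recovers a
  generating 4-month window in ≈ 95% of replicates.
* `fixed_reference`: the same lengths as the default, but anchored at the
  species' reference month as fixed calendar months for every specimen.

The fixed anchor matters for validation. When the window follows each
specimen's realised month, any date noise that pushes a specimen across a
month boundary drags its entire window onto climatologically warmer or
colder months — in spring the monthly climatology climbs ~5 °C per month —
so the covariate acquires an error component correlated with the response.
Under the generator's defaults this inflates fitted slopes by roughly
+2 days °C⁻¹ (the test suite measures the contrast between the two
anchors). The per-specimen anchor remains the default because it is
the method as practised; all ground-truth recovery checks use
`fixed_reference`, which matches the generator's cue window, and the
correlation screen offers the same fixed-anchor option.

## The synthetic generator

`scenario_config()` defaults describe the study design the analysis targets:
10 climate divisions observed 1895–2009 (one single-station division,
others 2–4 stations), a temperate-continental monthly climatology with a
0.9 °C linear warming over the record, 141 species totalling roughly 5000
specimens (10–235 each, right-skewed), and season-level mean responsiveness
of −2.5 / −1.4 / −0.6 days °C⁻¹ (spring / early summer / late summer) with
a 1.5 days °C⁻¹ between-species SD. Remaining constants are realistic
choices documented here: monthly division anomalies with SD 2 °C (shared by
a division's stations) plus 0.5 °C independent station noise; a 7-day
residual SD on flowering day; 5% duplicate and 5% non-peak record
injection; collector names drawn from a small pool but kept unique per
original record so the dedupe stage removes exactly the injected
duplicates. Species deviations can be drawn from a λ-scaled Brownian
covariance of a simulated birth–death tree (unit depth) to plant
phylogenetic signal. Everything is reproducible from one seed.

Each specimen's flowering day is intercept + ρ × (windowed division
temperature for its year and division) + Gaussian noise, realised as a
calendar date. Because dates are integer days, the noise-free limit recovers
ρ to the rounding scale (~0.1 days °C⁻¹), not machine precision; exactness
of the OLS mechanics is asserted separately on continuous constructed
inputs.

What the generator does **not** emulate: spatially autocorrelated climate
fields (divisions are independent), collection-effort bias through time,
flowering-duration differences among species, and any real taxonomy. Passing
recovery tests therefore show the estimators are correct and calibrated
under the stated design, not that any particular empirical dataset meets
those assumptions.

## Problem sizes used in validation

The test suite exercises: 500 synthetic species (50 specimens each,
temperature SD 1.5 °C, residual SD 7 days, true ρ = −3) for slope bias and
95% CI coverage; 200 cohort screens at the 141-species scale for window
recovery; 500 null replicates (60 species × 30 specimens) for the type-I
error of the slope-contrast LR test plus one full-scale effect recovery; and
100 replicates each of Brownian (λ = 1) and independent (λ = 0) traits on
128-tip trees for λ recovery. These sizes keep the whole suite to a few
minutes on one CPU while leaving Monte-Carlo error well inside the asserted
bands.

## Known limitations

* The per-specimen window anchor carries the month-boundary confound
  described above; results from sparse, late-season, or weakly responsive
  species lean most on it.
* LR p-values use the chi-squared reference; with few species per group the
  test can be mildly liberal, and the notation "df" always means the
  fixed-effect parameter-count difference.
* λ is profiled for an intercept-only model of ρ; trait covariates inside
  the GLS are out of scope.
* Specimens must arrive with an explicit division code; georeferencing
  free-text localities is out of scope.
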