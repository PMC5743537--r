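---
title: "Thermal spring phenology, breeding-time selection and demographic trends: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal spring phenology, breeding-time selection and demographic trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The scientific problem

Spring warming can desynchronise a breeding population from the seasonal
resources it depends on. For an insectivorous songbird this question has two
empirically distinct faces:

1. **Trends.** Over decades, does the thermal progression of spring advance
   faster than breeding time, and do selection for early breeding and
   demographic rates change in parallel?
2. **Annual variation.** Within the same data, do years in which breeding is
   thermally late (poorly matched) actually show weaker performance?

Parallel trends alone are inconclusive: any unrelated, slowly deteriorating
driver produces them too. `phenomatch` implements the full chain needed to
ask both questions — a thermal description of spring, a data-driven spring
indicator, matching measures, within-season selection estimates, trend
meta-regressions, and mixed models for demographic rates — plus a
synthetic-data generator in which either hypothesis can be planted and
recovered.

## Thermal sums and the spring indicator

A day contributes degree days $DD = \max(T_{mean} - T_{base}, 0)$; the
thermal sum $TS(d)$ is the running total of $DD$ from January 1 through day
$d$. Truncation is applied per day, before accumulation, so frost days never
subtract. Feb 29 is an ordinary accumulation day.

The *spring progression date* of a year is the first day on which $TS$
reaches a threshold $S$. Because different arthropod taxa develop at
different base temperatures, the indicator is selected by grid search:
$T_{base} \in \{-5, \dots, +10\}\,^\circ$C (1 °C steps; the range is
standard in insect phenology, the step is our choice and configurable) and
$S \in \{100, 200, \dots\}$ degree days, capped per base temperature at the
largest multiple of 100 not exceeding the minimum over years of the thermal
sum reached at that year's latest first-clutch lay date. The cap guarantees
every retained candidate crosses its threshold in every year; we interpret
the "end of egg laying" per year and take the minimum over years. Each
candidate is scored by the OLS regression of annual median lay date on its
crossing dates; the candidate with the largest $R^2$ wins. Exact ties (rare)
break deterministically — higher base temperature, then lower threshold —
and are logged in the grid report.

Candidates whose threshold is not reached in some year, or with fewer than
3 usable years, or with zero predictor variance, are excluded rather than
imputed.

## Matching measures

Population-level matching in year $y$ is measured two ways:

* **Day difference**: median lay date minus the spring-indicator date
  (positive = breeding later than thermal spring);
* **Thermal sum at breeding**: the annual median of individual thermal sums
  at lay (or hatch) date, computed at the winning indicator's base
  temperature (default 3 °C).

Both are computed on first attempts only. Annual medians use the *lower
median* (the order statistic at position $\lceil n/2 \rceil$), which keeps
medians on observed dates; the choice is documented and configurable.
Unobserved hatch dates are derived as `lay + (clutch − 1) + 13` days (one
egg per day, incubation from the last egg); incubation length is
configurable — the nestling period is fixed at 16 days as in the study
design the package mirrors. On data with strictly increasing within-year
thermal sums, the two measures are monotonically related; their Pearson
correlation (with $t$, $df = n-2$, $p$) is reported by
`correlate_matching_measures()`.

## Within-season selection and weighted trends

Per year and demographic rate, a GLM of the rate on *relative lay date*
(days since the year's earliest lay date) estimates a within-season slope —
selection for breeding time — and an intercept that reads as the earliest
breeder's expected performance. Families: binomial/logit for nest success
and adult survival, Poisson/log for fledgling and recruit counts, Gaussian
for nestling weight (canonical choices for these response types; the family
map is configurable because slope scales alone cannot disambiguate).
Analyses use first attempts including nests failed after hatching; nests
failed before hatching are excluded; years with fewer than 5 usable records,
complete separation, or non-convergence are flagged and excluded from the
trend stage. A quadratic-date AIC comparison (`linearity_check()`) is
informational only; the pipeline always uses linear slopes.

Annual slopes are then regressed on year (trend) or on the annual median
thermal sum at hatch (matching) by weighted least squares with weights
**literally 1/SE** of the yearly slope — the sample-size-related uncertainty
weighting of the original analysis — with an `inv_var` (1/SE²) switch for
sensitivity; a deviating weight rule is flagged in the run manifest. With
equal SEs the fit reduces exactly to OLS, which the tests assert against a
closed-form normal-equations oracle.

## Mixed models

Demographic rates and nestling weight are modelled at the record level with
crossed random intercepts for year, territory and individual (female; male
for male survival), fitted with `lme4` (the Laplace approximation for
binomial/Poisson; exact ML for Gaussian — ML by default so likelihood-ratio
tests on fixed effects are valid, REML available for variance reporting).
Trend models use year as the focal predictor with lay date, field layer,
age, nestling-period rain days and density (annual pairs) as covariates;
matching models replace year with the annual median thermal sum and lay
date with the individual thermal sum at hatch. Continuous covariates are
centred for conditioning; slopes are unchanged. Fits that fail `lme4`'s
convergence check are restarted once from the first optimum with
Nelder–Mead before a diagnostic error is raised; singular variance
estimates are returned with a `boundary` flag.

Gaussian fits report drop-one likelihood-ratio tests per fixed term
($\chi^2 = 2\,\Delta\log L$, $df = 1$); non-Gaussian fits report Wald $z$
p-values. Marginal and conditional $R^2$ follow the variance-partition
approach: $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_d)$ and
$R^2_c$ adds $\sigma^2_r$ to the numerator, with distribution-specific
variance $\sigma^2_d$ equal to the residual variance (Gaussian), $\pi^2/3$
(binomial logit), or $\mathrm{trigamma}(\lambda)$ with $\lambda =
\exp(\bar\eta + \sigma^2_r/2)$ (Poisson log). The Poisson $\lambda$ uses the
mean fixed-effect linear predictor — a documented choice among the common
variants of this estimator.

Prediction bands use a parametric bootstrap: draw fixed effects from their
asymptotic normal distribution, simulate a response (random effects and
residuals redrawn from the fitted variances), refit, and predict at a grid
of focal values with other covariates at reference values and random
effects at zero; the band is the pointwise 2.5/50/97.5 percentile. Defaults:
$B = 1000$, seeded, failed refits skipped (error above 20% failures). The
band's stochastic coverage is not separately calibrated here; the unit
tests assert determinism under a fixed seed, band ordering, and collapse at
$B = 1$.

## The synthetic-data generator

`simulate_dataset()` produces a daily climate series and a breeding-record
table with the statistical structure the analysis assumes. What it emulates,
and the study conditions its defaults encode:

* **Climate**: seasonal sinusoid (coldest mid-January) + linear warming +
  AR(1) noise; defaults (mean 5.8 °C, amplitude 11 °C, innovation SD 2.2 °C,
  $\rho = 0.7$) put the (3 °C, 200 DD) crossing in early-to-mid May with a
  between-year SD near 6.6 days. The warming default, 0.12 °C/yr, was set so
  the expected spring advance over a 20-year study is about −0.6 d/yr,
  matching the advance the package's target system reports; the mismatch
  scenario warms at 0.18 °C/yr.
* **Phenology**: annual median lay = intercept + 0.424 × spring date +
  annual noise (SD 1.4 d, calibrated so the lay-date regression explains
  ≈ 0.78 of annual variance); individual lay dates Normal(median, 4 d).
* **Demography**: each rate follows its GLM family with a seasonal slope
  that starts distinctly negative and flattens across years
  (`slope_year_trend`, Table-1-scale), year trends at Table-2-scale
  magnitudes (e.g. −0.130 g/yr nestling weight, −0.082 logit/yr
  recruitment), covariate effects (field layer, female age, rain days,
  density) and crossed year/territory/individual random intercepts.
  Intercept declines plus slope flattening reproduce the strongly negative
  slope–intercept correlation of the field system.
* **Structure**: ~90 pairs/yr (Poisson), a territory pool 1.3× that with
  field-layer class fixed per territory, females and males persisting by
  their generated survival (returners aged "old"), clutch sizes uniform on
  {5, 6, 7}, some failed pairs renesting (non-first attempts exercise the
  filters), recruits binomially thinned from fledglings so
  recruits ≤ fledglings by construction, and per-nestling weighings at ages
  5–7 d with age and brood-size effects.

Scenarios: `baseline` and `deterioration` plant year trends with **zero**
dependence on matching (the "general deterioration" world); under them,
matching-focal models should find nothing — though because warming gives the
matching covariate its own trend, a small negative leakage of the year
trend into the matching coefficient is expected and visible, which is
precisely why trend evidence alone is inconclusive. `mismatch_trend` plants
the converse: no intrinsic year trends, rates depending negatively on the
individual thermal sum at breeding, and faster warming so thermal delay
grows.

What the generator does **not** emulate: food abundance or arthropod
phenology, spatial structure and dispersal, density feedbacks, observation
error in dates, non-Gaussian weather regimes. Passing recovery tests
therefore show the *estimators* are correct under the assumed generative
structure, not that the structure captures every property of field data.

## Numerical choices and degenerate inputs

* Missing climate days: linear interpolation across gaps ≤ 3 days
  (interpolated days get 0 mm rain and are flagged); longer gaps error, as
  silently bridging them would distort cumulative sums. How the original
  climate series handled gaps is unknown; this rule is ours.
* Degree-day accumulation uses `cumsum` (extended-precision accumulation);
  the test oracle checks bit-exact agreement with a naive loop on
  quarter-degree inputs and tolerance-level agreement on continuous inputs.
* Zero-variance predictors, all-equal lay dates, constant responses,
  separation and non-convergence are flagged, excluded from downstream
  stages, and reported — never imputed.
* All randomness is seeded; `run_pipeline()` writes a config hash and seed
  into every output file, and identical inputs give byte-identical outputs.

## Problem sizes used by the test-suite and acceptance script

Recovery and calibration checks run at the study's own scale — 20-year,
~90-pair datasets — with 100 replicates for the indicator/tracking sweep,
10 replicates for GLMM effect recovery, and 1000 (tests) or 200 (script)
null simulations for LRT calibration. Two documented limits of the
prescribed conditions are worth knowing: with residual lay noise calibrated
to $R^2 \approx 0.78$, the exact winning candidate is genuinely ambiguous
among near-collinear grid neighbours, so exact-recovery rates sit near
40–50%, and the per-replicate probability that a 20-year slope estimate
falls within ±2 estimated SEs of truth is about 94% ($t_{18}$), not 95%.
The package reports both honestly rather than tuning the conditions.

## Known limitations

* Apparent survival conflates mortality with permanent emigration; the
  package models it as a binary outcome, with no capture–mark–recapture
  machinery.
* The weighted trend regression conditions on estimated yearly slopes; no
  errors-in-variables correction is applied beyond the 1/SE weighting.
* Wald SEs for trends estimated across ~20 group levels ignore
  variance-estimate uncertainty and run ~10–15% small; REML helps the
  variance bias but not this. Ensemble (multi-replicate) summaries are the
  reliable recovery check.
* The bootstrap band reflects fixed-effect uncertainty and sampling noise,
  not uncertainty in the random-effect variances themselves.
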