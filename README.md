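# phenomatch

Tools for asking whether a warming spring has demographic consequences for
a seasonally breeding bird population: does the thermal progression of
spring outpace breeding time, and — the sharper question — do years of poor
phenological matching actually show weaker selection for early breeding or
lower demographic rates?

The package targets long-term nest-record studies (single population,
~20 years, ~90 pairs/yr) with a nearby daily climate series. It was built
around the biology of a ground-nesting migratory songbird, but every
constant (incubation length, grids, families) is configurable.

## What it computes

1. **Thermal sums.** Daily degree days `DD = max(Tmean − Tbase, 0)`
   accumulated from January 1 give a thermal sum `TS(d)` for every day; the
   spring progression date of a year is the first day `TS ≥ S`.
2. **Spring indicator by grid search.** Candidates over
   `Tbase ∈ {−5..+10} °C` and `S ∈ {100, 200, …}` (capped at the thermal sum
   reached by the end of egg laying) are scored by the OLS regression of
   annual median lay date on crossing date; the largest R² wins.
3. **Phenological matching.** Per year: the day difference between median
   lay date and the spring date (positive = thermally late breeding), and
   the annual median of individual thermal sums at lay/hatch. The two
   measures are nearly interchangeable (Pearson r reported).
4. **Within-season selection.** Per year and rate (nest success, nestling
   weight, fledglings, recruits, adult survival), a GLM on lay date
   relative to the year's earliest breeder gives a selection slope and an
   earliest-breeder intercept; annual slopes are then regressed on year or
   on matching with weights 1/SE (weighted trend meta-regression).
5. **Mixed models.** Record-level GLMMs with crossed random intercepts
   (year, territory, individual) estimate year trends (or matching effects)
   in each rate, with drop-one LRTs, Wald z tests, marginal/conditional R²
   (variance partition), and parametric-bootstrap prediction bands.
6. **Synthetic data.** A scenario-based generator (`baseline`,
   `deterioration`, `mismatch_trend`) plants known truths for every stage,
   so estimator correctness is testable without field data.

## Worked example

```r
library(phenomatch)

sim <- simulate_dataset("baseline", seed = 42)   # 20 years, ~90 pairs/yr
ind <- derive_spring_indicator(sim$climate, sim$records)
ind
#> <spring_indicator> t_base 5.0 C, threshold 100 DD; lay ~ crossing:
#>   slope 0.351 (SE 0.034), r2 0.852 over 20 years

an <- annual_matching(sim$records, sim$climate, ind)
correlate_matching_measures(an)
#> <correlation> r = 0.940, t = 11.71, df = 18, p = 7.43e-10

est <- fit_yearly_selection(sim$records, "recruits")
weighted_trend(est, "year")
#> <trend_fit> recruits ~ year (w = inv_se): estimate 0.00465 (SE 0.00161),
#>   t = 2.89, p = 0.00971, r2 = 0.317, 20 years
weighted_trend(est, "median_ts", matching = an)
#> <trend_fit> recruits ~ median_ts (w = inv_se): estimate 0.00033
#>   (SE 0.00021), t = 1.56, p = 0.136, r2 = 0.119, 20 years
slope_intercept_correlation(est)
#> <correlation> r = -0.830, t = -6.32, df = 18, p = 5.83e-06
```

Reading the output: the grid search picks a spring indicator explaining 85%
of annual lay-date variance — here a near-neighbour of the planted
(3 °C, 200 DD) driver, a reminder that adjacent candidates track the same
spring and are genuinely hard to tell apart at realistic noise. The two
matching measures correlate at r = 0.94. Selection slopes for recruitment
flatten significantly across years (+0.0046 per year on the logit-day
scale, p ≈ 0.01) while showing no relationship with annual matching
(p ≈ 0.14), and the strongly negative slope–intercept correlation (−0.83)
says the flattening is driven by declining early-breeder performance — the
generator's deterioration structure, recovered.

The full pipeline, including the GLMMs and report files with provenance
headers, runs from a config:

```r
cfg <- pipeline_config("climate.csv", "breeding.csv", "nestlings.csv",
                       out_dir = "results", seed = 1)
res <- run_pipeline(cfg)
```

or from the shell via `Rscript inst/cli/phenomatch.R simulate|run-all …`.

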