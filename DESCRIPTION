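Package: phenomatch
Title: Thermal-Sum Spring Phenology, Breeding-Time Selection and
    Demographic Trends in Songbird Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the thermal progression of spring from daily
    temperature series (accumulated degree-day sums), derive the spring
    indicator that best predicts annual median lay dates by grid search over
    base temperatures and thermal-sum thresholds, measure phenological
    matching between breeding time and thermal spring at the population and
    individual level, estimate within-season selection for breeding time as
    yearly GLM slopes with 1/SE-weighted trend meta-regressions, and fit
    crossed random-intercept GLMMs for demographic rates and nestling weight
    with likelihood-ratio tests, marginal/conditional R-squared and
    parametric-bootstrap prediction bands. Includes a scenario-based
    synthetic-data generator (climate plus breeding records) so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
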