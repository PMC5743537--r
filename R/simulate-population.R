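#' Per-rate generative parameters (linear-predictor scale)
#'
#' One row per demographic rate. Columns: `intercept` (linear predictor for
#' the earliest breeder in the first study year at reference covariates),
#' `seasonal_slope` (per day of relative lay date), `slope_year_trend`
#' (change of the seasonal slope per year — flattening selection),
#' `year_trend` (per year), `matching_effect` (per degree day of individual
#' thermal sum at hatch, centred), covariate effects (`eff_field_layer` for
#' tall territories, `eff_female_age` for young females, `eff_rain` per rain
#' day, `eff_density` per territory), and random-intercept SDs for year,
#' territory and individual. Scales: logit for nest success, adult survival
#' and per-fledgling recruitment probability; log for fledgling counts;
#' grams for nestling weight. Default magnitudes are anchored to the
#' long-term field study this generator emulates (e.g. nestling weight
#' declining by about 0.13 g per year, per-fledgling recruitment by about
#' 0.08 logits per year).
#'
#' @return data frame with one row per rate of [phenomatch_rates()].
#' @export
default_rate_params <- function() {
  data.frame(
    rate = c("nest_success", "nestling_weight", "fledglings", "recruits",
             "male_survival", "female_survival"),
    intercept       = c( 3.20,  5.80,  1.80, -0.70,  0.60,  0.30),
    seasonal_slope  = c(-0.080, -0.050, -0.025, -0.050, -0.040, -0.012),
    slope_year_trend = c(0.006, 0.004, 0.002, 0.004, 0.006, 0.001),
    year_trend      = c(-0.088, -0.130, -0.021, -0.082, -0.020, -0.035),
    matching_effect = c(0, 0, 0, 0, 0, 0),
    eff_field_layer = c(-0.588, -0.282, -0.146, -0.313, -0.077, 0.036),
    eff_female_age  = c(-0.088, -0.280, -0.026, -0.051, -0.113, -0.076),
    eff_rain        = c(-0.165, -0.082, -0.032, -0.090, -0.040, -0.006),
    eff_density     = c(0.002, -0.006, -0.0004, -0.013, -0.009, -0.012),
    sd_year         = c(0.30, 0.45, 0.12, 0.25, 0.20, 0.20),
    sd_territory    = c(0.30, 0.35, 0.10, 0.20, 0.15, 0.15),
    sd_individual   = c(0.30, 0.55, 0.15, 0.25, 0.20, 0.20),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic breeding-population generator
#'
#' The generator plants a known truth for every pipeline stage: annual
#' median lay dates track the crossing date of a fixed internal spring
#' driver (base temperature 3 C, threshold 200 degree days) with slope
#' `lay_tracking_slope`; individual lay dates scatter around the annual
#' median; demographic outcomes follow per-rate GLMM structures with
#' seasonal slopes, year trends, covariate effects and crossed random
#' intercepts (year, territory, individual). In the trend scenarios the
#' within-season slopes start distinctly negative and flatten across years
#' (`slope_year_trend`) while intercepts (earliest-breeder performance)
#' decline with the year trends, reproducing the strongly negative
#' slope-intercept correlation of the field system.
#'
#' @param scenario `"baseline"`, `"deterioration"` or `"mismatch_trend"`;
#'   see [scenario_presets()].
#' @param years study years (must be covered by the climate series).
#' @param pairs_per_year mean breeding pairs per year (default 90).
#' @param lay_intercept intercept of the median-lay-on-spring-date relation
#'   (day of year).
#' @param lay_tracking_slope days of median lay per day of spring date
#'   (default 0.424).
#' @param lay_noise_sd SD of annual median lay dates around the tracking
#'   line, days. The default (1.4) is calibrated so the lay-date regression
#'   on the spring driver explains roughly 78% of the annual variance under
#'   the default climate.
#' @param within_year_lay_sd SD of individual lay dates within a year, days.
#' @param clutch_range possible clutch sizes (discrete uniform).
#' @param incubation_days,nestling_period_days breeding schedule constants
#'   (13 and 16 days).
#' @param driver internal spring driver, list(t_base, threshold).
#' @param matching_center centring constant (degree days) for the
#'   individual-thermal-sum effect.
#' @param rain_center centring constant for the rain-day covariate.
#' @param renest_prob probability that a failed first attempt renests.
#' @param fail_before_hatch_prob probability that a failed nest failed
#'   before hatching.
#' @param territory_pool_factor territory pool size relative to
#'   `pairs_per_year` (partial reuse across years).
#' @param w_age_effect,w_brood_effect,w_resid_sd nestling-weight model
#'   constants: grams per day of nestling age, grams per brood member, and
#'   residual SD.
#' @param rate_params per-rate parameter table, see [default_rate_params()].
#' @return list of class `population_gen_config`.
#' @export
population_gen_config <- function(scenario = "baseline", years = 1993:2012,
                                  pairs_per_year = 90, lay_intercept = 78,
                                  lay_tracking_slope = 0.424,
                                  lay_noise_sd = 1.4, within_year_lay_sd = 4,
                                  clutch_range = 5:7, incubation_days = 13L,
                                  nestling_period_days = 16L,
                                  driver = list(t_base = 3, threshold = 200),
                                  matching_center = 300, rain_center = 5.6,
                                  renest_prob = 0.5,
                                  fail_before_hatch_prob = 0.55,
                                  territory_pool_factor = 1.3,
                                  w_age_effect = 2.213, w_brood_effect = -0.191,
                                  w_resid_sd = 1.1,
                                  rate_params = default_rate_params()) {
  if (pairs_per_year <= 0) stop("population_gen_config(): pairs_per_year > 0", call. = FALSE)
  structure(list(scenario = scenario, years = years,
                 pairs_per_year = pairs_per_year, lay_intercept = lay_intercept,
                 lay_tracking_slope = lay_tracking_slope,
                 lay_noise_sd = lay_noise_sd,
                 within_year_lay_sd = within_year_lay_sd,
                 clutch_range = clutch_range, incubation_days = incubation_days,
                 nestling_period_days = nestling_period_days, driver = driver,
                 matching_center = matching_center, rain_center = rain_center,
                 renest_prob = renest_prob,
                 fail_before_hatch_prob = fail_before_hatch_prob,
                 territory_pool_factor = territory_pool_factor,
                 w_age_effect = w_age_effect, w_brood_effect = w_brood_effect,
                 w_resid_sd = w_resid_sd, rate_params = rate_params),
            class = "population_gen_config")
}

#' Named generator scenarios
#'
#' * `baseline` — the study-like world: year trends in all rates and a
#'   flattening of within-season slopes over years, no dependence of rates
#'   on thermal matching; tracking slope 0.424.
#' * `deterioration` — identical trend structure, named explicitly for the
#'   dissociation test: rates decline with year while matching effects are
#'   exactly zero, so matching-focal models should find nothing.
#' * `mismatch_trend` — the converse: no intrinsic year trends, rates depend
#'   negatively on the individual thermal sum at breeding, and (paired with
#'   a faster-warming climate) breeding is increasingly delayed in thermal
#'   terms, so matching-focal models should find negative effects.
#'
#' @param name scenario name.
#' @return a [population_gen_config()].
#' @export
scenario_presets <- function(name) {
  known <- c("baseline", "deterioration", "mismatch_trend")
  if (!name %in% known) {
    stop("scenario_presets(): unknown scenario '", name, "'; presets: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  cfg <- population_gen_config(scenario = name)
  if (name == "mismatch_trend") {
    rp <- cfg$rate_params
    rp$year_trend <- 0
    rp$slope_year_trend <- 0
    rp$matching_effect <- c(-0.0020, -0.0080, -0.0009, -0.0020,
                            -0.0010, -0.0014)
    cfg$rate_params <- rp
  }
  cfg
}

#' Climate configuration matched to a scenario
#'
#' `mismatch_trend` warms faster (0.18 C/yr) than the default 0.12 C/yr so
#' that spring advances faster than the lay response and thermal delay grows.
#'
#' @param scenario scenario name.
#' @param years study years.
#' @return a [climate_gen_config()].
#' @export
scenario_climate_config <- function(scenario = "baseline", years = 1993:2012) {
  climate_gen_config(
    years = years,
    warming_per_year = if (identical(scenario, "mismatch_trend")) 0.18 else 0.12)
}

#' Generate a synthetic breeding-record and nestling-weight table
#'
#' Implements the generative structure described in
#' [population_gen_config()]. Females and males persist across years
#' according to their generated survival (returners are aged "old", new
#' recruits "young"), territories are drawn from a pool ~1.3x the annual
#' number of pairs with field-layer class fixed per territory, and failed
#' first attempts may renest (`first_attempt = FALSE` rows exercise the
#' pipeline's filters). Recruits are binomially thinned from fledglings, so
#' `n_recruits <= n_fledglings` always holds.
#'
#' @param climate a [climate_series()] covering `config$years`.
#' @param config a [population_gen_config()].
#' @param seed RNG seed.
#' @return list of class `phenomatch_sim`: `records` (breeding-record data
#'   frame), `nestlings` (nest, nestling_age, weight, brood_size), `annual`
#'   (year, spring_doy, mu_lay, n_pairs — the planted truth) and the
#'   `config` and `seed` used.
#' @export
generate_population <- function(climate, config = population_gen_config(),
                                seed = 1L) {
  stopifnot(inherits(climate, "climate_series"),
            inherits(config, "population_gen_config"))
  if (!all(config$years %in% unique(climate$year))) {
    stop("generate_population(): climate does not cover config years", call. = FALSE)
  }
  set.seed(seed)
  rp <- config$rate_params
  rates <- rp$rate
  years <- config$years
  t_idx <- years - min(years)

  ts_driver <- lapply(stats::setNames(years, years), function(y) {
    thermal_sum_series(climate, config$driver$t_base, y)
  })
  spring <- vapply(years, function(y) {
    d <- date_of_threshold(ts_driver[[as.character(y)]], config$driver$threshold)
    if (is.na(d)) NA_real_ else as.numeric(date_to_doy(d))
  }, numeric(1))
  if (anyNA(spring)) {
    stop("generate_population(): spring driver threshold never reached in ",
         "some year(s); climate too cold", call. = FALSE)
  }
  mu_lay <- config$lay_intercept + config$lay_tracking_slope * spring +
    stats::rnorm(length(years), 0, config$lay_noise_sd)

  pool_n <- round(config$territory_pool_factor * config$pairs_per_year)
  terr_fl <- sample(c("short", "tall"), pool_n, replace = TRUE)
  terr_re <- matrix(stats::rnorm(pool_n * length(rates)), pool_n, length(rates))
  terr_re <- sweep(terr_re, 2L, rp$sd_territory, `*`)
  colnames(terr_re) <- rates

  id_cap <- config$pairs_per_year * length(years) * 2L
  ind_re_pool <- function() {
    m <- matrix(stats::rnorm(id_cap * length(rates)), id_cap, length(rates))
    m <- sweep(m, 2L, rp$sd_individual, `*`)
    colnames(m) <- rates
    m
  }
  fem_re <- ind_re_pool()
  mal_re <- ind_re_pool()
  # start with an established population: ~45% of first-year breeders are
  # returners ("old"), as in an ongoing study
  n_est <- round(0.45 * config$pairs_per_year)
  roster_f <- seq_len(n_est)
  roster_m <- seq_len(n_est)
  next_f <- n_est + 1L
  next_m <- n_est + 1L

  rain01 <- lapply(stats::setNames(years, years), function(y) {
    climate$precip[climate$year == y] > 0
  })

  recs <- list()
  nstl <- list()
  n_pairs_y <- integer(length(years))

  for (k in seq_along(years)) {
    y <- years[k]
    n_pairs <- max(20L, min(stats::rpois(1L, config$pairs_per_year), pool_n))
    n_pairs_y[k] <- n_pairs

    n_ret_f <- min(length(roster_f), n_pairs)
    fem <- c(if (n_ret_f) sample(roster_f, n_ret_f) else integer(0),
             seq.int(next_f, length.out = n_pairs - n_ret_f))
    fem_age <- c(rep("old", n_ret_f), rep("young", n_pairs - n_ret_f))
    next_f <- next_f + (n_pairs - n_ret_f)
    n_ret_m <- min(length(roster_m), n_pairs)
    mal <- c(if (n_ret_m) sample(roster_m, n_ret_m) else integer(0),
             seq.int(next_m, length.out = n_pairs - n_ret_m))
    mal_age <- c(rep("old", n_ret_m), rep("young", n_pairs - n_ret_m))
    next_m <- next_m + (n_pairs - n_ret_m)
    terr <- sample(pool_n, n_pairs, replace = FALSE)

    year_re <- stats::rnorm(length(rates), 0, rp$sd_year)
    names(year_re) <- rates

    draw_attempt <- function(lay_doy, clutch, first_attempt, surv_f = NULL,
                             surv_m = NULL, rel_lay) {
      hatch_doy <- lay_doy + (clutch - 1L) + config$incubation_days
      its_hatch <- ts_driver[[as.character(y)]]$values[hatch_doy]
      rain_days <- vapply(hatch_doy, function(h) {
        sum(rain01[[as.character(y)]][h:(h + config$nestling_period_days - 1L)])
      }, numeric(1))
      n <- length(lay_doy)
      eta <- function(rate, age_vec, re_ind) {
        p <- rp[rp$rate == rate, ]
        p$intercept +
          (p$seasonal_slope + p$slope_year_trend * t_idx[k]) * rel_lay +
          p$year_trend * t_idx[k] +
          p$matching_effect * (its_hatch - config$matching_center) +
          p$eff_field_layer * (terr_fl[terr] == "tall") +
          p$eff_female_age * (age_vec == "young") +
          p$eff_rain * (rain_days - config$rain_center) +
          p$eff_density * (n_pairs - config$pairs_per_year) +
          year_re[rate] + terr_re[terr, rate] + re_ind
      }
      success <- stats::rbinom(n, 1L, stats::plogis(
        eta("nest_success", fem_age, fem_re[fem, "nest_success"])))
      failed_before <- ifelse(success == 1L, FALSE,
                              stats::runif(n) < config$fail_before_hatch_prob)
      fledg <- ifelse(success == 1L,
                      pmin(pmax(stats::rpois(n, exp(
                        eta("fledglings", fem_age, fem_re[fem, "fledglings"]))), 1L),
                        clutch),
                      0L)
      recr <- stats::rbinom(n, fledg, stats::plogis(
        eta("recruits", fem_age, fem_re[fem, "recruits"])))
      if (is.null(surv_f)) {
        surv_f <- stats::rbinom(n, 1L, stats::plogis(
          eta("female_survival", fem_age, fem_re[fem, "female_survival"])))
        surv_m <- stats::rbinom(n, 1L, stats::plogis(
          eta("male_survival", mal_age, mal_re[mal, "male_survival"])))
      }
      list(success = success, failed_before = failed_before, fledg = fledg,
           recr = recr, surv_f = surv_f, surv_m = surv_m,
           hatch_doy = hatch_doy, rain_days = rain_days,
           eta_w = eta("nestling_weight", fem_age,
                       fem_re[fem, "nestling_weight"]))
    }

    lay1 <- round(stats::rnorm(n_pairs, mu_lay[k], config$within_year_lay_sd))
    lay1 <- pmin(pmax(lay1, 60L), 200L)
    clutch1 <- sample(config$clutch_range, n_pairs, replace = TRUE)
    rel1 <- lay1 - min(lay1)
    a1 <- draw_attempt(lay1, clutch1, TRUE, rel_lay = rel1)

    mk_rows <- function(lay_doy, clutch, a, first_attempt, suffix) {
      n <- length(lay_doy)
      data.frame(
        nest = sprintf("%d_%03d%s", y, seq_len(n), suffix),
        year = y, territory = sprintf("T%03d", terr),
        female = sprintf("F%05d", fem), male = sprintf("M%05d", mal),
        lay_date = doy_to_date(y, lay_doy), clutch_size = clutch,
        hatch_date = doy_to_date(y, a$hatch_doy),
        field_layer = terr_fl[terr],
        female_age = fem_age, male_age = mal_age,
        nest_success = a$success, n_fledglings = a$fledg,
        n_recruits = a$recr, female_survival = a$surv_f,
        male_survival = a$surv_m, rain_days = a$rain_days,
        first_attempt = first_attempt,
        failed_before_hatching = a$failed_before,
        stringsAsFactors = FALSE
      )
    }
    rows <- mk_rows(lay1, clutch1, a1, TRUE, "")

    renest <- which(a1$success == 0L & stats::runif(n_pairs) < config$renest_prob)
    if (length(renest)) {
      lay2 <- pmin(lay1[renest] + 18L, 200L)
      clutch2 <- pmax(clutch1[renest] - 1L, min(config$clutch_range))
      keep_f <- fem; keep_m <- mal; keep_terr <- terr
      keep_fa <- fem_age; keep_ma <- mal_age
      fem <- fem[renest]; mal <- mal[renest]; terr <- terr[renest]
      fem_age <- fem_age[renest]; mal_age <- mal_age[renest]
      a2 <- draw_attempt(lay2, clutch2, FALSE,
                         surv_f = a1$surv_f[renest], surv_m = a1$surv_m[renest],
                         rel_lay = lay2 - min(lay1))
      rows2 <- mk_rows(lay2, clutch2, a2, FALSE, "r")
      fem <- keep_f; mal <- keep_m; terr <- keep_terr
      fem_age <- keep_fa; mal_age <- keep_ma
      rows <- rbind(rows, rows2)
    }
    recs[[k]] <- rows

    hatched <- which(!rows$failed_before_hatching)
    if (length(hatched)) {
      brood <- rows$clutch_size[hatched]
      age_n <- sample(5:7, length(hatched), replace = TRUE)
      fem_idx <- as.integer(sub("F", "", rows$female[hatched]))
      eta_w_rows <- c(a1$eta_w, if (length(renest)) a2$eta_w)[hatched]
      nstl[[k]] <- data.frame(
        nest = rep(rows$nest[hatched], brood),
        nestling_age = rep(age_n, brood),
        brood_size = rep(brood, brood),
        weight = rep(eta_w_rows, brood) +
          config$w_age_effect * rep(age_n, brood) +
          config$w_brood_effect * rep(brood, brood) +
          stats::rnorm(sum(brood), 0, config$w_resid_sd),
        stringsAsFactors = FALSE
      )
    }

    first_rows <- rows[rows$first_attempt, ]
    roster_f <- unique(as.integer(sub("F", "",
      first_rows$female[first_rows$female_survival == 1L])))
    roster_m <- unique(as.integer(sub("M", "",
      first_rows$male[first_rows$male_survival == 1L])))
  }

  structure(
    list(records = do.call(rbind, recs),
         nestlings = do.call(rbind, nstl),
         annual = data.frame(year = years, spring_doy = spring,
                             mu_lay = mu_lay, n_pairs = n_pairs_y),
         config = config, seed = seed),
    class = "phenomatch_sim"
  )
}

#' One-call scenario dataset (climate + population)
#'
#' @param scenario scenario name, see [scenario_presets()].
#' @param seed RNG seed (climate uses `seed`, population `seed + 1`).
#' @param years study years.
#' @param pairs_per_year mean pairs per year.
#' @return a `phenomatch_sim` list with an additional `climate` element.
#' @export
simulate_dataset <- function(scenario = "baseline", seed = 1L,
                             years = 1993:2012, pairs_per_year = 90) {
  pcfg <- scenario_presets(scenario)
  pcfg$years <- years
  pcfg$pairs_per_year <- pairs_per_year
  climate <- generate_climate(scenario_climate_config(scenario, years), seed)
  sim <- generate_population(climate, pcfg, seed + 1L)
  sim$climate <- climate
  sim
}

#' @export
print.phenomatch_sim <- function(x, ...) {
  cat(sprintf("<phenomatch_sim> scenario '%s': %d attempts, %d nestling rows, years %d-%d\n",
              x$config$scenario, nrow(x$records), nrow(x$nestlings),
              min(x$config$years), max(x$config$years)))
  invisible(x)
}
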