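breeding_columns <- function() {
  c("nest", "year", "territory", "female", "male", "lay_date", "clutch_size",
    "hatch_date", "field_layer", "female_age", "male_age", "nest_success",
    "n_fledglings", "n_recruits", "female_survival", "male_survival",
    "rain_days", "first_attempt", "failed_before_hatching")
}

#' Read a breeding-record CSV
#'
#' One row per nest attempt; columns as in [breeding_columns()], dates
#' ISO-8601. Rows violating record invariants (hatch date not after lay
#' date, recruits exceeding fledglings, rain days outside 0..16, clutch size
#' below 1) are rejected and reported, not silently kept: the returned data
#' frame carries a `rejected` attribute naming each bad row and the reason.
#'
#' @param path CSV path (`#` comment lines ignored).
#' @param nestling_period_days upper bound for the rain-day count (default 16).
#' @return validated breeding-record data frame; attribute `rejected` is a
#'   data frame (`row`, `nest`, `reason`) of dropped rows.
#' @export
read_breeding_csv <- function(path, nestling_period_days = 16L) {
  if (!file.exists(path)) stop("read_breeding_csv(): no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- breeding_columns()
  miss <- setdiff(req, names(raw))
  extra <- setdiff(names(raw), req)
  if (length(miss)) {
    stop("read_breeding_csv(): schema mismatch; missing: ",
         paste(miss, collapse = ", "),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  raw$lay_date <- as.Date(raw$lay_date)
  raw$hatch_date <- as.Date(raw$hatch_date)
  raw$first_attempt <- as.logical(raw$first_attempt)
  raw$failed_before_hatching <- as.logical(raw$failed_before_hatching)
  reasons <- character(nrow(raw))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }
  bad(is.na(raw$lay_date), "unparseable lay_date")
  bad(!is.na(raw$hatch_date) & raw$hatch_date <= raw$lay_date,
      "hatch_date not after lay_date")
  bad(raw$n_recruits > raw$n_fledglings, "recruits exceed fledglings")
  bad(raw$rain_days < 0 | raw$rain_days > nestling_period_days,
      "rain_days outside nestling period")
  bad(raw$clutch_size < 1, "clutch_size below 1")
  drop <- reasons != ""
  rejected <- data.frame(row = which(drop), nest = raw$nest[drop],
                         reason = reasons[drop], stringsAsFactors = FALSE)
  out <- raw[!drop, req, drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Read a nestling-weight CSV (`nest`, `nestling_age`, `weight`, `brood_size`)
#' @param path CSV path.
#' @return data frame.
#' @export
read_nestling_csv <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("nest", "nestling_age", "weight", "brood_size")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("read_nestling_csv(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw
}

#' Pipeline configuration
#'
#' @param climate_csv,breeding_csv,nestling_csv input paths (`nestling_csv`
#'   optional; without it nestling-weight analyses are skipped).
#' @param out_dir output directory (NULL = return results only).
#' @param t_base_grid,threshold_step spring-indicator search grid.
#' @param weight_rule trend-regression weights, `"inv_se"` (the default
#'   1/SE rule) or `"inv_var"`.
#' @param incubation_days hatch-date derivation constant.
#' @param min_records minimum records per yearly selection fit.
#' @param run_glmm fit the mixed models (can be slow on large data).
#' @param seed seed recorded in all output provenance.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(climate_csv, breeding_csv, nestling_csv = NULL,
                            out_dir = NULL, t_base_grid = -5:10,
                            threshold_step = 100, weight_rule = "inv_se",
                            incubation_days = 13L, min_records = 5L,
                            run_glmm = TRUE, seed = 1L, log_level = "info") {
  structure(list(climate_csv = climate_csv, breeding_csv = breeding_csv,
                 nestling_csv = nestling_csv, out_dir = out_dir,
                 t_base_grid = t_base_grid, threshold_step = threshold_step,
                 weight_rule = weight_rule, incubation_days = incubation_days,
                 min_records = min_records, run_glmm = run_glmm, seed = seed,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read and validate all pipeline inputs
#'
#' @param config a [pipeline_config()].
#' @return list: `climate` ([climate_series()]), `records`, `nestlings`
#'   (NULL if not configured), `rejected` row report.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  climate <- read_climate_csv(config$climate_csv)
  records <- read_breeding_csv(config$breeding_csv)
  nestlings <- if (!is.null(config$nestling_csv)) {
    read_nestling_csv(config$nestling_csv)
  }
  list(climate = climate, records = records, nestlings = nestlings,
       rejected = attr(records, "rejected"))
}

pipeline_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf(paste0("[phenomatch] ", fmt), ...))
  }
}

#' Assemble the mixed-model analysis table
#'
#' First attempts with failed-before-hatching nests excluded, plus the
#' model covariates: years since study start (`year_c`), lay day of year,
#' individual thermal sum at hatch, the annual median thermal sum at hatch
#' (`median_ts`) and density (annual pairs). Continuous covariates are
#' centred (slopes unchanged; the intercept becomes the value at covariate
#' means), which keeps the crossed-random-effect fits well conditioned;
#' centres are recorded in the `centers` attribute.
#'
#' @param records breeding-record data frame.
#' @param nestlings nestling table (may be NULL; join it yourself for
#'   nestling-weight fits).
#' @param climate a [climate_series()].
#' @param indicator a `spring_indicator`.
#' @param annual an [annual_matching()] summary.
#' @param incubation_days hatch-date derivation constant.
#' @return data frame ready for [fit_glmm()].
#' @export
glmm_table <- function(records, nestlings, climate, indicator, annual,
                       incubation_days = 13L) {
  d <- records[records$first_attempt & !records$failed_before_hatching, ,
               drop = FALSE]
  d$year_c <- d$year - min(d$year)
  d$lay_doy <- date_to_doy(d$lay_date)
  d$individual_ts <- individual_thermal_sum(d, climate, indicator$t_base,
                                            "hatch", incubation_days)
  d$median_ts <- annual$match_median_ts_hatch[match(d$year, annual$year)]
  d$density <- annual$n_pairs[match(d$year, annual$year)]
  centers <- c(lay_doy = mean(d$lay_doy), density = mean(d$density),
               median_ts = mean(d$median_ts),
               individual_ts = mean(d$individual_ts))
  for (v in names(centers)) d[[v]] <- d[[v]] - centers[[v]]
  attr(d, "centers") <- centers
  d
}

#' Standard model specification for one demographic rate
#'
#' Year-trend models (`focal = "year_c"`) use year, lay date and the
#' standard covariates (field layer, age, rain days, density; survival
#' models add nest success; nestling weight adds nestling age and brood
#' size); matching models (`focal = "median_ts"`) replace year with the
#' annual median thermal sum and lay date with the individual thermal sum.
#' Random intercepts: year, territory, and female (male for male survival).
#'
#' @param rate one of [phenomatch_rates()].
#' @param focal `"year_c"` or `"median_ts"`.
#' @param families named family map, see [default_families()].
#' @return a [model_spec()].
#' @export
glmm_spec_for <- function(rate, focal = c("year_c", "median_ts"),
                          families = default_families()) {
  focal <- match.arg(focal)
  indiv <- if (rate == "male_survival") "male" else "female"
  fixed <- if (focal == "year_c") {
    c("year_c", "lay_doy", "field_layer",
      if (rate == "male_survival") "male_age" else "female_age",
      "rain_days", "density")
  } else {
    c("median_ts", "individual_ts", "field_layer",
      if (rate == "male_survival") "male_age" else "female_age",
      "rain_days", "density")
  }
  if (rate %in% c("female_survival", "male_survival")) {
    fixed <- append(fixed, "nest_success", after = 1L)
  }
  if (rate == "nestling_weight") fixed <- c(fixed, "nestling_age", "brood_size")
  model_spec(response = response_column(rate), family = families[[rate]],
             fixed = fixed, random = c("year", "territory", indiv),
             focal = focal)
}

#' Run the full analysis pipeline
#'
#' Orchestrates thermal sums, spring-indicator grid search, annual matching,
#' yearly selection slopes with 1/SE-weighted trend regressions (on year and
#' on the matching measure), slope-intercept correlations, and (optionally)
#' the crossed random-intercept GLMMs with year or matching as focal
#' predictor. When `config$out_dir` is set, writes the report bundle (grid
#' report, annual summary, selection estimates, trend tables, per-model fit
#' reports) with a provenance header (config hash + seed) on every file,
#' plus a run manifest JSON. Identical inputs and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return list: `indicator`, `annual`, `match_cor`, `estimates`,
#'   `trends_year`, `trends_matching`, `slope_intercept`, `glmm_year`,
#'   `glmm_matching`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- read_inputs(config)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  prov <- sprintf("phenomatch config_hash=%s seed=%d", hash, config$seed)
  pipeline_log(config, "inputs: %d climate days, %d records (%d rejected)",
               nrow(inputs$climate), nrow(inputs$records),
               nrow(inputs$rejected))

  indicator <- derive_spring_indicator(inputs$climate, inputs$records,
                                       config$t_base_grid,
                                       config$threshold_step)
  pipeline_log(config, "spring indicator: t_base %.1f, threshold %.0f, r2 %.3f",
               indicator$t_base, indicator$threshold, indicator$r2)

  annual <- annual_matching(inputs$records, inputs$climate, indicator,
                            config$incubation_days)
  match_cor <- correlate_matching_measures(annual)

  rates <- phenomatch_rates()
  if (is.null(inputs$nestlings)) rates <- setdiff(rates, "nestling_weight")
  estimates <- list()
  trends_year <- list()
  trends_matching <- list()
  si_cor <- list()
  for (rate in rates) {
    for (cs in c("none", "standard")) {
      est <- fit_yearly_selection(inputs$records, rate, cs,
                                  nestlings = inputs$nestlings,
                                  min_n = config$min_records)
      estimates[[paste(rate, cs, sep = ".")]] <- est
      ty <- tryCatch(weighted_trend(est, "year", weight_rule = config$weight_rule),
                     error = function(e) NULL)
      tm <- tryCatch(weighted_trend(est, "median_ts", matching = annual,
                                    weight_rule = config$weight_rule),
                     error = function(e) NULL)
      trends_year[[paste(rate, cs, sep = ".")]] <- ty
      trends_matching[[paste(rate, cs, sep = ".")]] <- tm
      if (cs == "none") {
        si_cor[[rate]] <- tryCatch(slope_intercept_correlation(est),
                                   error = function(e) NULL)
      }
    }
  }
  est_all <- do.call(rbind, estimates)
  rownames(est_all) <- NULL
  pipeline_log(config, "selection: %d yearly estimates (%d flagged)",
               nrow(est_all), sum(est_all$flag != "ok"))

  glmm_year <- list()
  glmm_matching <- list()
  glmm_failures <- character()
  if (isTRUE(config$run_glmm)) {
    gdat <- glmm_table(inputs$records, inputs$nestlings, inputs$climate,
                       indicator, annual, config$incubation_days)
    for (rate in rates) {
      d <- gdat
      if (rate == "nestling_weight") d <- merge(d, inputs$nestlings, by = "nest")
      d <- d[!is.na(d[[response_column(rate)]]), , drop = FALSE]
      for (focal in c("year_c", "median_ts")) {
        spec <- glmm_spec_for(rate, focal)
        fit <- tryCatch(suppressWarnings(fit_glmm(d, spec)),
                        error = function(e) {
                          glmm_failures <<- c(glmm_failures,
                                              sprintf("%s/%s: %s", rate, focal,
                                                      conditionMessage(e)))
                          NULL
                        })
        if (focal == "year_c") glmm_year[[rate]] <- fit
        else glmm_matching[[rate]] <- fit
      }
    }
    pipeline_log(config, "glmm: %d fits, %d failures",
                 2L * length(rates) - length(glmm_failures),
                 length(glmm_failures))
  }

  manifest <- list(
    package = "phenomatch",
    version = as.character(utils::packageVersion("phenomatch")),
    r_version = R.version.string,
    seed = config$seed, config_hash = hash,
    weight_rule = config$weight_rule,
    weight_rule_deviates = !identical(config$weight_rule, "inv_se"),
    n_records = nrow(inputs$records), n_rejected = nrow(inputs$rejected),
    indicator = list(t_base = indicator$t_base,
                     threshold = indicator$threshold, r2 = indicator$r2),
    glmm_failures = glmm_failures
  )

  result <- list(indicator = indicator, annual = annual,
                 match_cor = match_cor, estimates = est_all,
                 trends_year = trends_year, trends_matching = trends_matching,
                 slope_intercept = si_cor, glmm_year = glmm_year,
                 glmm_matching = glmm_matching, manifest = manifest)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir, prov)
  }
  result
}

trend_table <- function(trends) {
  rows <- lapply(names(trends), function(nm) {
    tr <- trends[[nm]]
    if (is.null(tr)) return(NULL)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(rate = parts[1L], covariate_set = parts[2L],
               predictor = tr$predictor, estimate = tr$estimate, se = tr$se,
               t = tr$t, p = tr$p, r2 = tr$r2, n_years = tr$n_years,
               weight_rule = tr$weight_rule, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(result, out_dir, prov) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_csv_with_header(result$indicator$grid, p("grid_report.csv"), prov)
  write_csv_with_header(result$annual, p("annual_summary.csv"), prov)
  write_csv_with_header(result$estimates, p("selection_estimates.csv"), prov)
  ty <- trend_table(result$trends_year)
  if (!is.null(ty)) write_csv_with_header(ty, p("trend_year.csv"), prov)
  tm <- trend_table(result$trends_matching)
  if (!is.null(tm)) write_csv_with_header(tm, p("trend_matching.csv"), prov)
  for (rate in names(result$glmm_year)) {
    if (!is.null(result$glmm_year[[rate]])) {
      write_fit_report(result$glmm_year[[rate]],
                       p(sprintf("glmm_year_%s", rate)), prov)
    }
  }
  for (rate in names(result$glmm_matching)) {
    if (!is.null(result$glmm_matching[[rate]])) {
      write_fit_report(result$glmm_matching[[rate]],
                       p(sprintf("glmm_matching_%s", rate)), prov)
    }
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a simulated dataset to CSV files
#'
#' Writes the climate, breeding-record and nestling-weight CSVs of a
#' [simulate_dataset()] result, plus a provenance JSON with the full
#' generator configuration and seed.
#'
#' @param sim a `phenomatch_sim` with a `climate` element.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output paths.
#' @export
write_simulated_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "phenomatch_sim"), !is.null(sim$climate))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("phenomatch simulated scenario=%s seed=%d",
                  sim$config$scenario, sim$seed)
  cl <- file.path(out_dir, "climate.csv")
  br <- file.path(out_dir, "breeding.csv")
  ns <- file.path(out_dir, "nestlings.csv")
  pj <- file.path(out_dir, "provenance.json")
  write_climate_csv(sim$climate, cl, prov)
  rec <- sim$records
  rec$lay_date <- format(rec$lay_date, "%Y-%m-%d")
  rec$hatch_date <- format(rec$hatch_date, "%Y-%m-%d")
  write_csv_with_header(rec, br, prov)
  write_csv_with_header(sim$nestlings, ns, prov)
  jsonlite::write_json(
    list(scenario = sim$config$scenario, seed = sim$seed,
         config = sim$config[setdiff(names(sim$config), "rate_params")],
         rate_params = sim$config$rate_params),
    pj, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(cl, br, ns, pj))
}
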