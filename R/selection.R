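#' Demographic rates handled by the selection and mixed-model machinery
#' @export
phenomatch_rates <- function() {
  c("nest_success", "nestling_weight", "fledglings", "recruits",
    "male_survival", "female_survival")
}

#' Default GLM family per demographic rate
#'
#' Binary rates (nest success, adult survival) use binomial with logit link;
#' counts (fledglings, recruits) Poisson with log link; nestling weight
#' Gaussian with identity link. Configurable because slope scales alone
#' cannot disambiguate the original choice.
#'
#' @return named character vector rate -> family.
#' @export
default_families <- function() {
  c(nest_success = "binomial", nestling_weight = "gaussian",
    fledglings = "poisson", recruits = "poisson",
    male_survival = "binomial", female_survival = "binomial")
}

#' Lay dates relative to the year's earliest breeder
#'
#' Subtracts the minimum lay date, so the earliest breeder maps to 0 and a
#' model intercept reflects the performance of the earliest breeder.
#'
#' @param lay_dates Date (or numeric day-of-year) vector for one year.
#' @return numeric days since the earliest lay date.
#' @export
relative_lay_date <- function(lay_dates) {
  if (length(lay_dates) == 0L) stop("relative_lay_date(): no records", call. = FALSE)
  as.numeric(lay_dates - min(lay_dates))
}

response_column <- function(rate) {
  switch(rate,
         nest_success = "nest_success", fledglings = "n_fledglings",
         recruits = "n_recruits", male_survival = "male_survival",
         female_survival = "female_survival", nestling_weight = "weight",
         stop("unknown rate: ", rate, call. = FALSE))
}

# Analysis rows for one rate: first attempts, nests failed before hatching
# excluded (failed-after-hatching kept). Nestling weight joins the per-
# nestling weighing table.
selection_data <- function(records, rate, nestlings = NULL) {
  d <- records[records$first_attempt & !records$failed_before_hatching, ,
               drop = FALSE]
  if (rate == "nestling_weight") {
    if (is.null(nestlings)) {
      stop("selection_data(): nestling_weight needs the nestlings table",
           call. = FALSE)
    }
    d <- merge(d, nestlings, by = "nest")
  }
  d$y <- d[[response_column(rate)]]
  d <- d[!is.na(d$y), , drop = FALSE]
  d
}

selection_formula <- function(rate, covariate_set) {
  rhs <- "rel_lay"
  if (covariate_set == "standard") {
    rhs <- paste(rhs, "+ field_layer + female_age + rain_days")
    if (rate == "nestling_weight") rhs <- paste(rhs, "+ nestling_age + brood_size")
  }
  stats::as.formula(paste("y ~", rhs))
}

#' Yearly within-season selection estimates for one demographic rate
#'
#' Fits, per year, a GLM of the rate on lay date expressed relative to the
#' earliest lay date of that year ([relative_lay_date()]), giving the yearly
#' within-season slope (selection for breeding time) and intercept (earliest-
#' breeder performance). Uses first nest attempts including nests that failed
#' after hatching; nests that failed before hatching are excluded.
#'
#' @param records breeding-record data frame.
#' @param rate one of [phenomatch_rates()].
#' @param covariate_set `"none"` (slopes comparable across studies) or
#'   `"standard"` (adds field layer, female age and nestling-period rain
#'   days; nestling-weight models also add nestling age and brood size).
#' @param nestlings per-nestling weighing table (needed for
#'   `rate = "nestling_weight"`): columns `nest`, `nestling_age`, `weight`,
#'   `brood_size`.
#' @param min_n minimum usable records per year (default 5); smaller years
#'   are flagged and excluded from downstream trend regressions.
#' @param families named family map, see [default_families()].
#' @return data frame of class `selection_estimates`: `year`, `rate`,
#'   `covariate_set`, `slope`, `slope_se`, `intercept`, `n`, `flag`
#'   (`"ok"` or an exclusion reason).
#' @export
fit_yearly_selection <- function(records, rate, covariate_set = c("none", "standard"),
                                 nestlings = NULL, min_n = 5L,
                                 families = default_families()) {
  covariate_set <- match.arg(covariate_set)
  fam <- families[[rate]]
  d_all <- selection_data(records, rate, nestlings)
  fml <- selection_formula(rate, covariate_set)
  out <- lapply(sort(unique(d_all$year)), function(y) {
    d <- d_all[d_all$year == y, , drop = FALSE]
    n_units <- if (rate == "nestling_weight") length(unique(d$nest)) else nrow(d)
    row <- data.frame(year = y, rate = rate, covariate_set = covariate_set,
                      slope = NA_real_, slope_se = NA_real_,
                      intercept = NA_real_, n = n_units, flag = "ok",
                      stringsAsFactors = FALSE)
    if (n_units < min_n) {
      row$flag <- "too-few-records"
      return(row)
    }
    d$rel_lay <- relative_lay_date(d$lay_date)
    if (stats::var(d$y) == 0) {
      if (fam == "gaussian") {
        row$slope <- 0; row$intercept <- d$y[1L]; row$flag <- "zero-residual"
      } else {
        row$flag <- "constant-response"
      }
      return(row)
    }
    warns <- character()
    fit <- withCallingHandlers(
      tryCatch(stats::glm(fml, family = fam, data = d),
               error = function(e) NULL),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(fit) || !fit$converged) {
      row$flag <- "nonconvergence"
      return(row)
    }
    cf <- summary(fit)$coefficients
    row$slope <- cf["rel_lay", 1L]
    row$slope_se <- cf["rel_lay", 2L]
    row$intercept <- cf["(Intercept)", 1L]
    if (fam == "binomial" &&
        (any(grepl("fitted probabilities numerically 0 or 1", warns)) ||
         abs(row$slope) > 15 || row$slope_se > 25)) {
      row$flag <- "separation"
    }
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("selection_estimates", "data.frame")
  res
}

#' Weighted trend regression of yearly selection slopes
#'
#' Regresses yearly slopes (or any yearly estimate) on year or on the annual
#' matching measure, weighting each year by 1/SE of its estimate — the
#' literal sample-size-related uncertainty weight (a `weight_rule` switch to
#' classical inverse-variance 1/SE^2 is provided for sensitivity analysis).
#'
#' @param estimates a `selection_estimates` data frame (rows flagged other
#'   than `"ok"` are dropped).
#' @param predictor `"year"` or `"median_ts"`.
#' @param matching annual-matching data frame ([annual_matching()]); required
#'   when `predictor = "median_ts"`, joined by year, using the median thermal
#'   sum at hatch date.
#' @param weight_rule `"inv_se"` (default) or `"inv_var"`.
#' @return list of class `trend_fit`: `rate`, `predictor`, `estimate`, `se`,
#'   `t`, `p`, `r2`, `intercept`, `n_years`, `weight_rule`, `weights`.
#' @export
weighted_trend <- function(estimates, predictor = c("year", "median_ts"),
                           matching = NULL, weight_rule = c("inv_se", "inv_var")) {
  predictor <- match.arg(predictor)
  weight_rule <- match.arg(weight_rule)
  est <- estimates[estimates$flag == "ok", , drop = FALSE]
  if (nrow(est) < 3L) stop("weighted_trend(): need >= 3 usable years", call. = FALSE)
  if (any(!is.finite(est$slope_se) | est$slope_se <= 0)) {
    stop("weighted_trend(): non-positive slope SE", call. = FALSE)
  }
  x <- if (predictor == "year") {
    est$year
  } else {
    if (is.null(matching)) {
      stop("weighted_trend(): matching summary required for median_ts", call. = FALSE)
    }
    matching$match_median_ts_hatch[match(est$year, matching$year)]
  }
  if (anyNA(x)) stop("weighted_trend(): predictor missing for some years", call. = FALSE)
  w <- if (weight_rule == "inv_se") 1 / est$slope_se else 1 / est$slope_se^2
  fit <- stats::lm(est$slope ~ x, weights = w)
  sm <- summary(fit)
  structure(
    list(rate = est$rate[1L], predictor = predictor,
         estimate = unname(stats::coef(fit)[2L]),
         se = sm$coefficients[2L, 2L], t = sm$coefficients[2L, 3L],
         p = sm$coefficients[2L, 4L], r2 = sm$r.squared,
         intercept = unname(stats::coef(fit)[1L]),
         n_years = nrow(est), weight_rule = weight_rule, weights = w),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s ~ %s (w = %s): estimate %.5f (SE %.5f), t = %.2f, p = %.3g, r2 = %.3f, %d years\n",
    x$rate, x$predictor, x$weight_rule, x$estimate, x$se, x$t, x$p, x$r2, x$n_years))
  invisible(x)
}

#' Correlation between yearly intercepts and slopes
#'
#' Pearson correlation across years between the intercepts (earliest-breeder
#' performance) and slopes of the no-covariate within-season models. A
#' strongly negative correlation indicates that flattening selection is
#' driven by deteriorating early-breeder performance.
#'
#' @param estimates a `selection_estimates` data frame.
#' @return a `correlation_result` (see [correlate_matching_measures()]).
#' @export
slope_intercept_correlation <- function(estimates) {
  est <- estimates[estimates$flag == "ok", , drop = FALSE]
  if (nrow(est) < 3L) stop("slope_intercept_correlation(): need >= 3 years", call. = FALSE)
  if (stats::var(est$slope) == 0 || stats::var(est$intercept) == 0) {
    stop("slope_intercept_correlation(): zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(est$intercept, est$slope)
  structure(list(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "correlation_result")
}

#' Linear versus quadratic lay-date effect (informational check)
#'
#' Compares, per year, the AIC of the linear-date GLM with one adding a
#' quadratic date term. The pipeline always uses linear slopes; this check
#' documents that the linear form is adequate.
#'
#' @inheritParams fit_yearly_selection
#' @param min_n_quad minimum records to attempt the quadratic fit (default 8).
#' @return data frame: `year`, `aic_linear`, `aic_quadratic`, `preferred`
#'   (`"linear"`, `"quadratic"` or `"skipped"`).
#' @export
linearity_check <- function(records, rate, nestlings = NULL, min_n_quad = 8L,
                            families = default_families()) {
  fam <- families[[rate]]
  d_all <- selection_data(records, rate, nestlings)
  out <- lapply(sort(unique(d_all$year)), function(y) {
    d <- d_all[d_all$year == y, , drop = FALSE]
    row <- data.frame(year = y, aic_linear = NA_real_, aic_quadratic = NA_real_,
                      preferred = "skipped", stringsAsFactors = FALSE)
    d$rel_lay <- if (nrow(d)) relative_lay_date(d$lay_date) else numeric()
    if (nrow(d) < min_n_quad || stats::var(d$y) == 0 ||
        length(unique(d$rel_lay)) < 3L) {
      return(row)
    }
    f1 <- suppressWarnings(stats::glm(y ~ rel_lay, family = fam, data = d))
    f2 <- suppressWarnings(stats::glm(y ~ rel_lay + I(rel_lay^2), family = fam,
                                      data = d))
    row$aic_linear <- stats::AIC(f1)
    row$aic_quadratic <- stats::AIC(f2)
    row$preferred <- if (row$aic_linear <= row$aic_quadratic) "linear" else "quadratic"
    row
  })
  do.call(rbind, out)
}
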