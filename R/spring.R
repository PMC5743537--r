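#' Candidate (base temperature, threshold) grid
#'
#' Builds the Cartesian search grid for the spring-progression indicator.
#' Thresholds run from `threshold_step` upwards in steps of `threshold_step`;
#' for each base temperature the ceiling is the largest multiple of the step
#' not exceeding the minimum, over years, of the thermal sum reached at that
#' year's end of egg laying (latest first-clutch lay date). This guarantees
#' every retained candidate can have a crossing date in every year.
#'
#' @param series a [climate_series()].
#' @param latest_lay data frame with columns `year` and `date` (latest lay
#'   date per year).
#' @param t_base_grid base temperatures to consider, degrees C (default
#'   -5..10 in 1 C steps).
#' @param threshold_step threshold increment, degree days (default 100).
#' @return data frame with columns `t_base`, `threshold`; attribute
#'   `empty_t_base` lists base temperatures whose ceiling fell below the
#'   first step (no candidates).
#' @export
candidate_grid <- function(series, latest_lay, t_base_grid = -5:10,
                           threshold_step = 100) {
  stopifnot(inherits(series, "climate_series"))
  if (length(t_base_grid) == 0L || threshold_step <= 0) {
    stop("candidate_grid(): empty t_base grid or non-positive step", call. = FALSE)
  }
  rows <- list()
  empty <- numeric()
  for (tb in t_base_grid) {
    ceil_ts <- min(vapply(seq_len(nrow(latest_lay)), function(i) {
      ts <- thermal_sum_series(series, tb, latest_lay$year[i])
      thermal_sum_at(ts, latest_lay$date[i])
    }, numeric(1)))
    top <- floor(ceil_ts / threshold_step) * threshold_step
    if (top < threshold_step) {
      empty <- c(empty, tb)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(t_base = tb, threshold = seq(threshold_step, top, by = threshold_step))
  }
  if (!length(rows)) stop("candidate_grid(): no candidates in grid", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "empty_t_base") <- empty
  out
}

#' Evaluate one spring-indicator candidate
#'
#' Regresses annual median lay date (day of year) on the candidate's annual
#' threshold-crossing date (day of year) by OLS.
#'
#' @param series a [climate_series()].
#' @param median_lay data frame with columns `year`, `lay_doy` (annual median
#'   lay date as day of year).
#' @param t_base base temperature, degrees C.
#' @param threshold thermal-sum threshold, degree days.
#' @param min_years minimum years with both a crossing date and a median lay
#'   date (default 3); candidates below are flagged invalid.
#' @param ts_by_year optional precomputed list of [thermal_sum_series()] for
#'   this `t_base`, named by year (grid-search speed-up).
#' @return list of class `candidate_indicator` with the crossing dates, fit
#'   statistics (`slope`, `intercept`, `slope_se`, `r2`), `n_years`, and a
#'   `valid` flag with `reason` when the candidate cannot enter selection
#'   (missing years, too few years, or a zero-variance predictor).
#' @export
evaluate_candidate <- function(series, median_lay, t_base, threshold,
                               min_years = 3L, ts_by_year = NULL) {
  years <- median_lay$year
  cross <- vapply(years, function(y) {
    ts <- if (!is.null(ts_by_year)) ts_by_year[[as.character(y)]]
          else thermal_sum_series(series, t_base, y)
    d <- date_of_threshold(ts, threshold)
    if (is.na(d)) NA_real_ else as.numeric(date_to_doy(d))
  }, numeric(1))
  out <- list(t_base = t_base, threshold = threshold, years = years,
              crossing_doy = cross, n_years = sum(!is.na(cross)),
              slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
              r2 = NA_real_, valid = FALSE, reason = "")
  class(out) <- "candidate_indicator"
  ok <- !is.na(cross) & !is.na(median_lay$lay_doy)
  if (anyNA(cross)) {
    out$reason <- "threshold not reached in all years"
    return(out)
  }
  if (sum(ok) < min_years) {
    out$reason <- "insufficient years"
    return(out)
  }
  if (stats::var(cross[ok]) == 0) {
    out$reason <- "zero-variance predictor"
    return(out)
  }
  fit <- stats::lm(median_lay$lay_doy[ok] ~ cross[ok])
  sm <- summary(fit)
  out$slope <- unname(stats::coef(fit)[2L])
  out$intercept <- unname(stats::coef(fit)[1L])
  out$slope_se <- sm$coefficients[2L, 2L]
  out$r2 <- sm$r.squared
  out$valid <- TRUE
  out
}

#' Grid search for the best spring-progression indicator
#'
#' Evaluates every candidate of [candidate_grid()] and selects the one whose
#' threshold-crossing dates explain the most variance in annual median lay
#' dates (see [select_best()]).
#'
#' @inheritParams candidate_grid
#' @param median_lay data frame with `year`, `lay_doy` columns.
#' @param min_years passed to [evaluate_candidate()].
#' @return a `spring_indicator` (see [select_best()]) whose `grid` element is
#'   the full provenance table (t_base, threshold, n_years, slope, slope_se,
#'   r2, valid, winner).
#' @export
spring_grid_search <- function(series, median_lay, latest_lay,
                               t_base_grid = -5:10, threshold_step = 100,
                               min_years = 3L) {
  grid <- candidate_grid(series, latest_lay, t_base_grid, threshold_step)
  cands <- vector("list", nrow(grid))
  for (tb in unique(grid$t_base)) {
    ts_by_year <- lapply(stats::setNames(median_lay$year, median_lay$year),
                         function(y) thermal_sum_series(series, tb, y))
    for (i in which(grid$t_base == tb)) {
      cands[[i]] <- evaluate_candidate(series, median_lay, tb, grid$threshold[i],
                                       min_years = min_years,
                                       ts_by_year = ts_by_year)
    }
  }
  select_best(cands)
}

#' Select the winning candidate indicator
#'
#' The winner is the valid candidate (crossing date in every year) with the
#' largest r2. Exact ties are broken deterministically: higher base
#' temperature first, then lower threshold; ties are recorded in the `ties`
#' attribute of the returned grid.
#'
#' @param candidates list of [evaluate_candidate()] results.
#' @return list of class `spring_indicator`: winning `t_base`, `threshold`,
#'   fit statistics, per-year crossing `dates` (data frame `year`,
#'   `spring_doy`), and the full `grid` data frame with a `winner` flag.
#' @export
select_best <- function(candidates) {
  grid <- do.call(rbind, lapply(candidates, function(cc) {
    data.frame(t_base = cc$t_base, threshold = cc$threshold,
               n_years = cc$n_years, slope = cc$slope, slope_se = cc$slope_se,
               r2 = cc$r2, valid = cc$valid,
               reason = cc$reason, stringsAsFactors = FALSE)
  }))
  if (!any(grid$valid)) stop("select_best(): no valid candidate", call. = FALSE)
  ord <- order(-grid$r2, -grid$t_base, grid$threshold, na.last = TRUE)
  ord <- ord[grid$valid[ord]]
  win <- ord[1L]
  ties <- ord[which(abs(grid$r2[ord] - grid$r2[win]) < .Machine$double.eps^0.5)]
  grid$winner <- seq_len(nrow(grid)) == win
  wc <- candidates[[win]]
  structure(
    list(t_base = wc$t_base, threshold = wc$threshold, slope = wc$slope,
         intercept = wc$intercept, slope_se = wc$slope_se, r2 = wc$r2,
         dates = data.frame(year = wc$years, spring_doy = wc$crossing_doy),
         grid = `attr<-`(grid, "ties",
                         grid[setdiff(ties, win), c("t_base", "threshold"), drop = FALSE])),
    class = "spring_indicator"
  )
}

#' Derive the spring indicator directly from breeding records
#'
#' Convenience wrapper: computes annual median (lower-median rule) and latest
#' first-attempt lay dates from a breeding-record table, then runs
#' [spring_grid_search()].
#'
#' @param series a [climate_series()].
#' @param records a breeding-record data frame (see [read_breeding_csv()]).
#' @inheritParams spring_grid_search
#' @export
derive_spring_indicator <- function(series, records, t_base_grid = -5:10,
                                    threshold_step = 100, min_years = 3L) {
  first <- records[records$first_attempt, , drop = FALSE]
  yrs <- sort(unique(first$year))
  med <- data.frame(
    year = yrs,
    lay_doy = vapply(yrs, function(y) {
      lower_median(date_to_doy(first$lay_date[first$year == y]))
    }, numeric(1))
  )
  latest <- data.frame(
    year = yrs,
    date = as.Date(vapply(yrs, function(y) {
      as.character(max(first$lay_date[first$year == y]))
    }, character(1)))
  )
  spring_grid_search(series, med, latest, t_base_grid, threshold_step, min_years)
}

#' @export
print.spring_indicator <- function(x, ...) {
  cat(sprintf(
    "<spring_indicator> t_base %.1f C, threshold %.0f DD; lay ~ crossing: slope %.3f (SE %.3f), r2 %.3f over %d years\n",
    x$t_base, x$threshold, x$slope, x$slope_se, x$r2, nrow(x$dates)))
  invisible(x)
}
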