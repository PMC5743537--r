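#' Degree days for one or more daily mean temperatures
#'
#' A day's degree-day contribution is the positive excess of its mean
#' temperature over the base temperature, `max(tmean - t_base, 0)`: days at or
#' below the base contribute nothing. Truncation happens per day, before any
#' accumulation, so cold days never cancel warm ones.
#'
#' @param tmean daily mean temperature(s), degrees C.
#' @param t_base base temperature, degrees C (scalar or vector recyclable
#'   against `tmean`).
#' @return non-negative degree days, same length as `tmean`.
#' @examples
#' degree_day(8, 3)  # 5
#' degree_day(-2, 3) # 0
#' @export
degree_day <- function(tmean, t_base) {
  if (!all(is.finite(tmean)) || !all(is.finite(t_base))) {
    stop("degree_day(): tmean and t_base must be finite", call. = FALSE)
  }
  pmax(tmean - t_base, 0)
}

#' Construct a validated daily climate series
#'
#' @param df data frame with columns `date` (Date), `tmean` (degrees C) and
#'   `precip` (mm, non-negative). Days must be consecutive within each year
#'   and every year must start on January 1 (accumulation origin).
#' @return the data frame, ordered by date, with class `climate_series`.
#' @export
climate_series <- function(df) {
  req <- c("date", "tmean", "precip")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("climate_series(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("climate_series(): empty series", call. = FALSE)
  df <- df[order(df$date), req, drop = FALSE]
  if (!inherits(df$date, "Date")) stop("climate_series(): date must be Date", call. = FALSE)
  if (anyDuplicated(df$date)) stop("climate_series(): duplicated dates", call. = FALSE)
  if (!all(is.finite(df$tmean))) stop("climate_series(): non-finite tmean", call. = FALSE)
  if (any(!is.finite(df$precip) | df$precip < 0)) {
    stop("climate_series(): precip must be finite and >= 0", call. = FALSE)
  }
  df$year <- date_year(df$date)
  for (y in unique(df$year)) {
    d <- df$date[df$year == y]
    if (date_to_doy(d[1L]) != 1L) {
      stop("climate_series(): year ", y, " does not start on Jan 1", call. = FALSE)
    }
    if (length(d) > 1L && any(diff(as.integer(d)) != 1L)) {
      stop("climate_series(): gaps in year ", y,
           " (interpolate with read_climate_csv first)", call. = FALSE)
    }
  }
  class(df) <- c("climate_series", "data.frame")
  df
}

#' @export
print.climate_series <- function(x, ...) {
  yrs <- range(x$year)
  cat(sprintf("<climate_series> %d days, years %d-%d, tmean %.1f..%.1f C\n",
              nrow(x), yrs[1], yrs[2], min(x$tmean), max(x$tmean)))
  invisible(x)
}

#' Cumulative thermal-sum series for one calendar year
#'
#' Accumulates positive degree days from January 1 through the last day of the
#' year present in the series, giving the thermal sum TS on every calendar day.
#'
#' @param series a [climate_series()].
#' @param t_base base temperature, degrees C.
#' @param year calendar year, fully present in `series`.
#' @return object of class `thermal_sum_series`: list with `year`, `t_base`,
#'   `dates` and non-decreasing cumulative `values` (degree days).
#' @export
thermal_sum_series <- function(series, t_base, year) {
  stopifnot(inherits(series, "climate_series"))
  d <- series[series$year == year, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("thermal_sum_series(): year ", year, " missing from series", call. = FALSE)
  }
  structure(
    list(year = as.integer(year), t_base = t_base, dates = d$date,
         values = cumsum(degree_day(d$tmean, t_base))),
    class = "thermal_sum_series"
  )
}

#' First date on which a thermal-sum threshold is reached
#'
#' @param ts a [thermal_sum_series()].
#' @param threshold thermal sum, degree days (> 0).
#' @return the first date with cumulative TS >= `threshold`, or `NA` (class
#'   Date) if the threshold is never reached that year. Absence is a valid
#'   result, not an error: cold years may never accumulate a large sum.
#' @export
date_of_threshold <- function(ts, threshold) {
  stopifnot(inherits(ts, "thermal_sum_series"))
  if (!is.finite(threshold) || threshold <= 0) {
    stop("date_of_threshold(): threshold must be > 0", call. = FALSE)
  }
  i <- match(TRUE, ts$values >= threshold)
  if (is.na(i)) as.Date(NA) else ts$dates[i]
}

#' Thermal sum on given dates
#'
#' @param ts a [thermal_sum_series()].
#' @param date Date vector; every element must fall inside the series year.
#' @return cumulative thermal sum (degree days) on each date.
#' @export
thermal_sum_at <- function(ts, date) {
  stopifnot(inherits(ts, "thermal_sum_series"))
  idx <- as.integer(date - ts$dates[1L]) + 1L
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(ts$values))) {
    stop("thermal_sum_at(): date outside year ", ts$year, call. = FALSE)
  }
  ts$values[idx]
}

#' @export
print.thermal_sum_series <- function(x, ...) {
  cat(sprintf("<thermal_sum_series> year %d, t_base %.1f C, annual TS %.1f DD\n",
              x$year, x$t_base, x$values[length(x$values)]))
  invisible(x)
}
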