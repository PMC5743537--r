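#' Lower median
#'
#' Median that always returns an observed value: for odd n the middle order
#' statistic, for even n the lower of the two middle order statistics. Used
#' for annual median lay dates and median thermal sums so that population
#' medians stay on actually observed dates / sums.
#'
#' @param x numeric vector (NAs dropped).
#' @return a single element of `x`, or `NA` if `x` is empty after NA removal.
#' @export
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[(n + 1L) %/% 2L]
}

#' Relative reduction between two predicted values
#'
#' Percentage decline of `end` relative to `start`: `100 * (start - end) / start`.
#' This is the quantity used to express how much a demographic rate declined
#' over a study period relative to its predicted value at the start.
#'
#' @param start predicted value at the start of the period (non-zero).
#' @param end predicted value at the end of the period.
#' @return reduction in percent (positive = decline).
#' @examples
#' percent_reduction(0.92, 0.71) # nest success declining by ~23%
#' @export
percent_reduction <- function(start, end) {
  if (!all(is.finite(start)) || !all(is.finite(end))) {
    stop("percent_reduction(): inputs must be finite", call. = FALSE)
  }
  if (any(start == 0)) stop("percent_reduction(): start must be non-zero", call. = FALSE)
  100 * (start - end) / start
}

# day-of-year (calendar-true, Feb 29 counted) and its inverse
date_to_doy <- function(date) as.POSIXlt(date)$yday + 1L

doy_to_date <- function(year, doy) {
  as.Date(paste0(year, "-01-01")) + (doy - 1)
}

date_year <- function(date) as.POSIXlt(date)$year + 1900L

# stable hash of an R object via its canonical JSON, for output provenance
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
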