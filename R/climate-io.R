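#' Read a daily climate CSV
#'
#' Expected columns: `date` (ISO-8601), `tmean_c`, `precip_mm`; one row per
#' day. Gaps of up to `max_gap` consecutive missing days are filled by linear
#' interpolation of temperature (interpolated days get 0 mm precipitation and
#' are flagged in the `interpolated` attribute); longer gaps are an error,
#' since silently bridging them would distort cumulative thermal sums.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @param max_gap largest run of missing days to interpolate (default 3).
#' @return a [climate_series()]; attribute `interpolated` lists filled dates.
#' @export
read_climate_csv <- function(path, max_gap = 3L) {
  if (!file.exists(path)) stop("read_climate_csv(): no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("date", "tmean_c", "precip_mm")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("read_climate_csv(): schema mismatch, missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("read_climate_csv(): empty climate file", call. = FALSE)
  df <- data.frame(date = as.Date(raw$date),
                   tmean = as.numeric(raw$tmean_c),
                   precip = as.numeric(raw$precip_mm))
  if (anyNA(df$date)) stop("read_climate_csv(): unparseable dates", call. = FALSE)
  df <- df[order(df$date), ]
  filled <- interpolate_climate_gaps(df, max_gap)
  out <- climate_series(filled$df)
  attr(out, "interpolated") <- filled$interpolated
  out
}

# Fill day gaps <= max_gap by linear interpolation of tmean; precip on filled
# days is 0. Longer gaps raise an error.
interpolate_climate_gaps <- function(df, max_gap = 3L) {
  gaps <- diff(as.integer(df$date))
  if (all(gaps == 1L)) return(list(df = df, interpolated = as.Date(character())))
  too_long <- which(gaps - 1L > max_gap)
  if (length(too_long)) {
    stop(sprintf("climate gap of %d days after %s exceeds max_gap = %d",
                 gaps[too_long[1L]] - 1L, df$date[too_long[1L]], max_gap),
         call. = FALSE)
  }
  full_dates <- seq(df$date[1L], df$date[nrow(df)], by = "day")
  tmean <- stats::approx(as.integer(df$date), df$tmean,
                         xout = as.integer(full_dates))$y
  precip <- rep(0, length(full_dates))
  precip[match(df$date, full_dates)] <- df$precip
  list(df = data.frame(date = full_dates, tmean = tmean, precip = precip),
       interpolated = setdiff_dates(full_dates, df$date))
}

setdiff_dates <- function(a, b) a[!a %in% b]

#' Write a climate series to CSV (schema of [read_climate_csv()])
#'
#' @param series a [climate_series()].
#' @param path output path.
#' @param provenance optional string written as a leading `#` comment.
#' @export
write_climate_csv <- function(series, path, provenance = NULL) {
  stopifnot(inherits(series, "climate_series"))
  out <- data.frame(date = format(series$date, "%Y-%m-%d"),
                    tmean_c = series$tmean, precip_mm = series$precip)
  write_csv_with_header(out, path, provenance)
}

write_csv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
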