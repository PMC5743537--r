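#' Configuration for the synthetic daily climate generator
#'
#' Defaults emulate a boreal-temperate station of the kind behind the study
#' system (annual mean around 6.5 C, winter minima near -5 C, summer maxima
#' near 17 C) with a linear warming trend and AR(1) day-to-day noise.
#'
#' @param years calendar years to generate (default 1993:2012, a 20-year
#'   study window).
#' @param mean_temp annual mean temperature, C.
#' @param seasonal_amplitude half-range of the seasonal sinusoid, C.
#' @param warming_per_year linear warming trend, C per year.
#' @param ar1_rho AR(1) autocorrelation of daily residuals, in [0, 1).
#' @param noise_sd innovation SD of the AR(1) residuals, C (> 0); the
#'   marginal daily SD is `noise_sd / sqrt(1 - ar1_rho^2)`.
#' @param rain_prob daily probability of measurable rain.
#' @return list of class `climate_gen_config`.
#' @export
climate_gen_config <- function(years = 1993:2012, mean_temp = 5.8,
                               seasonal_amplitude = 11, warming_per_year = 0.12,
                               ar1_rho = 0.7, noise_sd = 2.2, rain_prob = 0.35) {
  if (noise_sd <= 0) stop("climate_gen_config(): noise_sd must be > 0", call. = FALSE)
  if (ar1_rho < 0 || ar1_rho >= 1) stop("climate_gen_config(): ar1_rho in [0,1)", call. = FALSE)
  if (rain_prob < 0 || rain_prob > 1) stop("climate_gen_config(): rain_prob in [0,1]", call. = FALSE)
  structure(list(years = years, mean_temp = mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 warming_per_year = warming_per_year, ar1_rho = ar1_rho,
                 noise_sd = noise_sd, rain_prob = rain_prob),
            class = "climate_gen_config")
}

#' Generate a synthetic daily climate series
#'
#' Daily mean temperature is a seasonal sinusoid (coldest around January 15)
#' plus a linear warming trend and AR(1) noise; daily rain occurrence is
#' Bernoulli with gamma-distributed amounts. Reproducible under `seed`.
#'
#' @param config a [climate_gen_config()].
#' @param seed RNG seed.
#' @return a [climate_series()].
#' @export
generate_climate <- function(config = climate_gen_config(), seed = 1L) {
  stopifnot(inherits(config, "climate_gen_config"))
  set.seed(seed)
  dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
               as.Date(paste0(max(config$years), "-12-31")), by = "day")
  yr <- date_year(dates)
  doy <- date_to_doy(dates)
  seasonal <- config$mean_temp -
    config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  trend <- config$warming_per_year * (yr - min(config$years))
  innov <- stats::rnorm(length(dates), 0, config$noise_sd)
  noise <- as.numeric(stats::filter(innov, config$ar1_rho, method = "recursive"))
  rain <- ifelse(stats::runif(length(dates)) < config$rain_prob,
                 stats::rgamma(length(dates), shape = 0.8, scale = 5), 0)
  climate_series(data.frame(date = dates, tmean = seasonal + trend + noise,
                            precip = rain))
}
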