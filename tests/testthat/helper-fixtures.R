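# Small in-code fixtures shared across test files.

# climate series from a vector of daily mean temperatures starting Jan 1
toy_climate <- function(tmeans, year = 2000, precip = 0) {
  n <- length(tmeans)
  climate_series(data.frame(
    date = as.Date(paste0(year, "-01-01")) + seq_len(n) - 1L,
    tmean = tmeans,
    precip = rep_len(precip, n)
  ))
}

# multi-year climate: one constant daily temperature per year
toy_climate_years <- function(temps_by_year, years, days = 365L) {
  do.call(rbind, Map(function(tm, y) {
    nd <- if (y %% 4 == 0 && (y %% 100 != 0 || y %% 400 == 0)) 366L else days
    data.frame(date = as.Date(paste0(y, "-01-01")) + seq_len(nd) - 1L,
               tmean = tm, precip = 0)
  }, temps_by_year, years)) |> climate_series()
}

# minimal breeding-record table; lay_doy per record, one year unless given
toy_records <- function(lay_doy, year = 2000, nest_success = 1L,
                        n_fledglings = 3L, n_recruits = 1L,
                        clutch_size = 6L, first_attempt = TRUE,
                        failed_before_hatching = FALSE,
                        field_layer = "short", female_age = "old",
                        rain_days = 5L) {
  n <- length(lay_doy)
  yr <- rep_len(year, n)
  lay <- as.Date(paste0(yr, "-01-01")) + lay_doy - 1L
  cs <- rep_len(clutch_size, n)
  data.frame(
    nest = sprintf("N%03d", seq_len(n)), year = yr,
    territory = sprintf("T%02d", seq_len(n) %% 7L + 1L),
    female = sprintf("F%03d", seq_len(n)), male = sprintf("M%03d", seq_len(n)),
    lay_date = lay, clutch_size = cs, hatch_date = lay + (cs - 1L) + 13L,
    field_layer = rep_len(field_layer, n), female_age = rep_len(female_age, n),
    male_age = rep_len("old", n), nest_success = rep_len(nest_success, n),
    n_fledglings = rep_len(n_fledglings, n),
    n_recruits = rep_len(n_recruits, n),
    female_survival = rep_len(1L, n), male_survival = rep_len(1L, n),
    rain_days = rep_len(rain_days, n),
    first_attempt = rep_len(first_attempt, n),
    failed_before_hatching = rep_len(failed_before_hatching, n),
    stringsAsFactors = FALSE
  )
}

# independently coded naive degree-day accumulator (oracle)
naive_thermal_sum <- function(tmeans, t_base) {
  out <- numeric(length(tmeans))
  acc <- 0
  for (i in seq_along(tmeans)) {
    dd <- tmeans[i] - t_base
    if (dd < 0) dd <- 0
    acc <- acc + dd
    out[i] <- acc
  }
  out
}

# crossed-design simulator for nestling-weight-like Gaussian data
sim_gauss_crossed <- function(seed, n = 1200, n_years = 20, n_terr = 30,
                              n_ind = 150, beta_year = -0.130,
                              beta_age = 2.213, sd_year = 0.45,
                              sd_terr = 0.35, sd_ind = 0.55, sd_res = 1.1) {
  set.seed(seed)
  year <- sample(n_years, n, replace = TRUE)
  terr <- sample(n_terr, n, replace = TRUE)
  ind <- sample(n_ind, n, replace = TRUE)
  age <- sample(5:7, n, replace = TRUE)
  re_y <- rnorm(n_years, 0, sd_year)
  re_t <- rnorm(n_terr, 0, sd_terr)
  re_i <- rnorm(n_ind, 0, sd_ind)
  data.frame(
    weight = 6.7 + beta_year * (year - 1) + beta_age * age +
      re_y[year] + re_t[terr] + re_i[ind] + rnorm(n, 0, sd_res),
    year_c = year - 1, nestling_age = age,
    year = factor(year), territory = factor(terr), female = factor(ind)
  )
}

# closed-form weighted least squares oracle: beta = (X'WX)^-1 X'Wy
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  W <- diag(w)
  unname(solve(t(X) %*% W %*% X, t(X) %*% W %*% y)[, 1L])
}
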