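test_that("degree_day truncates at the base temperature per day", {
  expect_equal(degree_day(8, 3), 5)
  expect_equal(degree_day(3, 3), 0)
  expect_equal(degree_day(-2, 3), 0)
  expect_equal(degree_day(c(4, 2, 6), 3), c(1, 0, 3))
  expect_error(degree_day(NA_real_, 3), "finite")
  expect_error(degree_day(5, Inf), "finite")
})

test_that("thermal_sum_series accumulates positive degree days from Jan 1", {
  cl <- toy_climate(c(4, 2, 6, 3, 1))
  ts <- thermal_sum_series(cl, 3, 2000)
  expect_equal(ts$values, c(1, 1, 4, 4, 4))
  expect_equal(ts$year, 2000L)

  flat <- toy_climate(rep(3, 40))
  expect_equal(thermal_sum_series(flat, 3, 2000)$values, rep(0, 40))

  expect_error(thermal_sum_series(cl, 3, 1999), "missing")
})

test_that("thermal sums match an independently coded naive accumulator", {
  set.seed(41)
  for (i in 1:100) {
    # quarter-degree temperatures: every partial sum is exactly representable,
    # so the cumulative series must agree with the naive loop bit for bit
    tm <- round(rnorm(30, mean = runif(1, -2, 10), sd = 4) * 4) / 4
    tb <- round(runif(1, -5, 10) * 4) / 4
    cl <- toy_climate(tm)
    ts <- thermal_sum_series(cl, tb, 2000)
    expect_identical(ts$values, naive_thermal_sum(tm, tb))
    # final value = sum of positive degree days (sum-then-compare oracle)
    expect_equal(ts$values[30], sum(pmax(tm - tb, 0)))
  }
  # continuous temperatures: agreement to numerical tolerance
  for (i in 1:20) {
    tm <- rnorm(30, 5, 4)
    tb <- runif(1, -5, 10)
    ts <- thermal_sum_series(toy_climate(tm), tb, 2000)
    expect_equal(ts$values, naive_thermal_sum(tm, tb))
  }
})

test_that("date_of_threshold finds the first crossing or returns NA", {
  cl <- toy_climate(c(4, 2, 6, 3, 1))
  ts <- thermal_sum_series(cl, 3, 2000)
  expect_equal(date_of_threshold(ts, 4), as.Date("2000-01-03"))
  expect_true(is.na(date_of_threshold(ts, 100)))
  expect_equal(date_of_threshold(ts, 1), as.Date("2000-01-01"))
  expect_error(date_of_threshold(ts, 0), "> 0")
})

test_that("crossing dates are monotone in threshold and base temperature", {
  set.seed(7)
  for (i in 1:20) {
    cl <- toy_climate(rnorm(120, 6, 4))
    # threshold monotonicity at fixed t_base
    ts <- thermal_sum_series(cl, 3, 2000)
    d_prev <- as.Date("1900-01-01")
    for (s in c(10, 50, 100, 200)) {
      d <- date_of_threshold(ts, s)
      if (is.na(d)) break
      expect_gte(as.numeric(d - d_prev), 0)
      # crossing definition: TS >= s on the day, < s the day before
      expect_gte(thermal_sum_at(ts, d), s)
      if (d > cl$date[1]) expect_lt(thermal_sum_at(ts, d - 1), s)
      d_prev <- d
    }
    # t_base monotonicity at fixed threshold
    d_prev <- as.Date("1900-01-01")
    for (tb in c(-2, 1, 4, 7)) {
      d <- date_of_threshold(thermal_sum_series(cl, tb, 2000), 100)
      if (is.na(d)) break
      expect_gte(as.numeric(d - d_prev), 0)
      d_prev <- d
    }
  }
})

test_that("thermal_sum_at looks up cumulative sums and validates the year", {
  cl <- toy_climate(c(10, 2, 6, 3, 1))
  ts <- thermal_sum_series(cl, 3, 2000)
  expect_equal(thermal_sum_at(ts, as.Date("2000-01-01")), 7) # 10 - 3
  expect_equal(thermal_sum_at(ts, as.Date("2000-01-03")), 10)
  expect_equal(thermal_sum_at(ts, as.Date("2000-01-05")),
               ts$values[length(ts$values)])
  expect_error(thermal_sum_at(ts, as.Date("2001-01-01")), "outside")
})

test_that("leap-year days are ordinary accumulation days", {
  cl <- toy_climate(rep(5, 366), year = 2000) # 2000 is a leap year
  ts <- thermal_sum_series(cl, 3, 2000)
  expect_length(ts$values, 366)
  expect_equal(thermal_sum_at(ts, as.Date("2000-02-29")), 2 * 60)
  expect_equal(ts$values[366], 2 * 366)
})

test_that("climate CSV reading interpolates short gaps and rejects long ones", {
  days <- as.Date("2000-01-01") + 0:9
  df <- data.frame(date = format(days, "%Y-%m-%d"), tmean_c = 1:10,
                   precip_mm = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-c(4, 5), ], f, row.names = FALSE) # 2-day gap
  cl <- read_climate_csv(f)
  expect_equal(nrow(cl), 10L)
  expect_equal(cl$tmean, 1:10) # linear interpolation restores the ramp
  expect_equal(attr(cl, "interpolated"), days[4:5])

  write.csv(df[-(3:7), ], f, row.names = FALSE) # 5-day gap
  expect_error(read_climate_csv(f), "gap")
  write.csv(df[0, ], f, row.names = FALSE)
  expect_error(read_climate_csv(f), "empty")
  write.csv(data.frame(date = "2000-01-01", temp = 1), f, row.names = FALSE)
  expect_error(read_climate_csv(f), "tmean_c")
})
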