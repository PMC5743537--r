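test_that("relative lay dates are days since the earliest breeder", {
  d <- as.Date("2000-01-01") + c(130, 133, 140) - 1
  expect_equal(relative_lay_date(d), c(0, 3, 10))
  expect_equal(relative_lay_date(d[1]), 0)
  expect_equal(relative_lay_date(rep(d[1], 3)), c(0, 0, 0))
  expect_error(relative_lay_date(as.Date(character())), "no records")
})

test_that("yearly selection fits recover planted slopes and flag degeneracies", {
  set.seed(91)
  n <- 200
  rec <- toy_records(lay_doy = 120 + sample(0:20, n, replace = TRUE))
  eta <- 1.5 - 0.05 * relative_lay_date(rec$lay_date)
  rec$n_fledglings <- rpois(n, exp(eta))
  est <- fit_yearly_selection(rec, "fledglings")
  expect_equal(est$flag, "ok")
  expect_lt(abs(est$slope - (-0.05)), 2 * est$slope_se)
  # intercept predicts the earliest breeder's performance (link scale)
  ref <- glm(n_fledglings ~ relative_lay_date(lay_date), poisson, rec)
  expect_equal(est$intercept, unname(coef(ref)[1]))
  expect_equal(est$slope, unname(coef(ref)[2]))

  # binary all-success year: degenerate, excluded
  rec$nest_success <- 1L
  est2 <- fit_yearly_selection(rec, "nest_success")
  expect_equal(est2$flag, "constant-response")
  expect_true(is.na(est2$slope))

  # constant Gaussian response via nestlings: slope 0, zero-residual flag
  nst <- data.frame(nest = rec$nest, nestling_age = 6L, weight = 15,
                    brood_size = 5L)
  est3 <- fit_yearly_selection(rec, "nestling_weight", nestlings = nst)
  expect_equal(est3$flag, "zero-residual")
  expect_equal(est3$slope, 0)

  # too few records
  est4 <- fit_yearly_selection(rec[1:4, ], "fledglings")
  expect_equal(est4$flag, "too-few-records")
})

test_that("selection fits use first attempts and drop failed-before-hatching nests", {
  rec <- toy_records(lay_doy = 120:139)
  rec$first_attempt[1:5] <- FALSE
  rec$failed_before_hatching[6:8] <- TRUE
  d <- phenomatch:::selection_data(rec, "fledglings")
  expect_equal(nrow(d), 12L)
})

test_that("weighted_trend matches the closed-form 1/SE WLS oracle", {
  est <- data.frame(year = 1:4, rate = "fledglings", covariate_set = "none",
                    slope = c(-0.10, -0.05, 0.00, 0.02),
                    slope_se = c(0.02, 0.02, 0.04, 0.04),
                    intercept = 0, n = 50, flag = "ok",
                    stringsAsFactors = FALSE)
  tr <- weighted_trend(est, "year")
  orc <- wls_oracle(est$year, est$slope, 1 / est$slope_se)
  expect_equal(tr$intercept, orc[1], tolerance = 1e-10)
  expect_equal(tr$estimate, orc[2], tolerance = 1e-10)

  # equal SEs reduce exactly to ordinary least squares
  est$slope_se <- 0.03
  tr_eq <- weighted_trend(est, "year")
  ols <- lm(slope ~ year, est)
  expect_equal(tr_eq$estimate, unname(coef(ols)[2]))
  expect_equal(tr_eq$se, summary(ols)$coefficients[2, 2])

  # three collinear points: r2 = 1 regardless of weights
  est3 <- est[1:3, ]
  est3$slope <- c(0.1, 0.2, 0.3)
  est3$slope_se <- c(0.01, 0.05, 0.02)
  expect_equal(suppressWarnings(weighted_trend(est3, "year")$r2), 1)

  # inverse-variance switch changes the fit but keeps the interface
  tr_iv <- weighted_trend(est3, "year", weight_rule = "inv_var")
  expect_equal(tr_iv$weight_rule, "inv_var")

  est$slope_se[1] <- 0
  expect_error(weighted_trend(est, "year"), "non-positive")
  expect_error(weighted_trend(est[1:2, ], "year"), ">= 3")
})

test_that("trend on the matching measure joins annual summaries by year", {
  est <- data.frame(year = 2001:2005, rate = "recruits", covariate_set = "none",
                    slope = c(-0.08, -0.05, -0.02, 0.01, 0.03),
                    slope_se = 0.02, intercept = 0, n = 50, flag = "ok",
                    stringsAsFactors = FALSE)
  an <- data.frame(year = 2001:2005,
                   match_median_ts_hatch = c(700, 720, 690, 750, 710))
  tr <- weighted_trend(est, "median_ts", matching = an)
  orc <- wls_oracle(an$match_median_ts_hatch, est$slope, 1 / est$slope_se)
  expect_equal(tr$estimate, orc[2], tolerance = 1e-10)
  expect_error(weighted_trend(est, "median_ts"), "matching")
})

test_that("slope-intercept correlation separates structure from noise", {
  est <- data.frame(year = 1:10, rate = "recruits", covariate_set = "none",
                    slope = seq(-0.1, 0.08, length.out = 10),
                    slope_se = 0.02, n = 50, flag = "ok",
                    stringsAsFactors = FALSE)
  est$intercept <- -est$slope
  expect_equal(slope_intercept_correlation(est)$r, -1)

  # independent slopes and intercepts: correlation near zero
  set.seed(17)
  big <- data.frame(year = 1:1000, rate = "x", covariate_set = "none",
                    slope = rnorm(1000), slope_se = 0.02,
                    intercept = rnorm(1000), n = 50, flag = "ok",
                    stringsAsFactors = FALSE)
  expect_lt(abs(slope_intercept_correlation(big)$r), 0.1)

  # early-breeder deterioration: intercepts fall, slopes flatten -> strongly negative
  sim <- simulate_dataset("deterioration", seed = 23)
  est_sim <- fit_yearly_selection(sim$records, "nest_success")
  expect_lt(slope_intercept_correlation(est_sim)$r, -0.5)
})

test_that("linearity check prefers the generating form", {
  set.seed(55)
  lin_wins <- 0L
  quad_wins <- 0L
  for (i in 1:10) {
    rec <- toy_records(lay_doy = 120 + sample(0:24, 150, replace = TRUE))
    rl <- relative_lay_date(rec$lay_date)
    rec$n_fledglings <- rpois(150, exp(1.4 - 0.04 * rl))
    lc <- linearity_check(rec, "fledglings")
    lin_wins <- lin_wins + (lc$preferred == "linear")
    rec$n_fledglings <- rpois(150, exp(1.4 - 0.012 * (rl - 12)^2 * 0.5))
    qc <- linearity_check(rec, "fledglings")
    quad_wins <- quad_wins + (qc$preferred == "quadratic")
  }
  expect_gte(lin_wins, 7L)
  expect_gte(quad_wins, 7L)
  # too small for the quadratic comparison
  rec_small <- toy_records(lay_doy = c(120, 125, 131))
  expect_equal(linearity_check(rec_small, "fledglings")$preferred, "skipped")
})
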