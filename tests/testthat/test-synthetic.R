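test_that("climate generation is seeded and deterministic", {
  cfg <- climate_gen_config(years = 2000:2004)
  a <- generate_climate(cfg, seed = 3)
  b <- generate_climate(cfg, seed = 3)
  expect_identical(a, b)
  c_ <- generate_climate(cfg, seed = 4)
  expect_false(identical(a$tmean, c_$tmean))
  expect_s3_class(a, "climate_series")
  expect_equal(min(a$date), as.Date("2000-01-01"))
  expect_equal(max(a$date), as.Date("2004-12-31"))
})

test_that("with vanishing noise the series is the seasonal curve plus trend", {
  cfg <- climate_gen_config(years = 2001:2003, warming_per_year = 0.12,
                            noise_sd = 1e-9)
  cl <- generate_climate(cfg, seed = 1)
  y1 <- cl$tmean[cl$year == 2001]
  y2 <- cl$tmean[cl$year == 2002]
  # same day of year, one year apart: difference is the warming trend
  expect_equal(y2 - y1, rep(0.12, 365), tolerance = 1e-6)
  expect_equal(which.min(y1), 15) # coldest around Jan 15
})

test_that("warming advances threshold-crossing dates in expectation", {
  advance <- replicate(12, {
    cl <- generate_climate(climate_gen_config(years = 2000:2019,
                                              warming_per_year = 0.12),
                           seed = sample.int(1e6, 1))
    doy <- sapply(2000:2019, function(y) {
      d <- date_of_threshold(thermal_sum_series(cl, 3, y), 200)
      as.POSIXlt(d)$yday + 1
    })
    mean(doy[16:20]) - mean(doy[1:5])
  })
  expect_lt(mean(advance), 0)
})

test_that("scenario presets encode the three generative hypotheses", {
  base <- scenario_presets("baseline")
  expect_equal(base$lay_tracking_slope, 0.424)
  expect_true(all(base$rate_params$matching_effect == 0))
  expect_true(all(base$rate_params$year_trend < 0))

  det <- scenario_presets("deterioration")
  expect_true(all(det$rate_params$matching_effect == 0))
  expect_true(all(det$rate_params$year_trend < 0))

  mis <- scenario_presets("mismatch_trend")
  expect_true(all(mis$rate_params$year_trend == 0))
  expect_true(all(mis$rate_params$matching_effect < 0))

  expect_error(scenario_presets("utopia"), "presets")
})

test_that("generated records satisfy the demographic invariants", {
  sim <- simulate_dataset("baseline", seed = 13, years = 2000:2009,
                          pairs_per_year = 60)
  r <- sim$records
  expect_true(all(r$n_recruits <= r$n_fledglings))
  expect_true(all(r$nest_success %in% 0:1))
  expect_true(all(r$female_survival %in% 0:1))
  expect_true(all(r$male_survival %in% 0:1))
  expect_true(all(r$hatch_date > r$lay_date))
  expect_true(all(r$rain_days >= 0 & r$rain_days <= 16))
  expect_true(all(r$field_layer %in% c("short", "tall")))
  expect_true(all(table(r$year[r$first_attempt]) >= 20))
  # nestling rows only for nests that reached hatching
  hatched <- r$nest[!r$failed_before_hatching]
  expect_true(all(sim$nestlings$nest %in% hatched))
  # renesting rows are flagged non-first attempts by failed pairs
  expect_true(all(!r$first_attempt[grepl("r$", r$nest)]))

  # determinism under a fixed seed
  sim2 <- simulate_dataset("baseline", seed = 13, years = 2000:2009,
                           pairs_per_year = 60)
  expect_identical(sim$records, sim2$records)
})

test_that("a null generator yields seasonal slopes centred on zero", {
  pcfg <- scenario_presets("baseline")
  rp <- pcfg$rate_params
  rp$seasonal_slope <- 0
  rp$slope_year_trend <- 0
  rp$year_trend <- 0
  pcfg$rate_params <- rp
  climate <- generate_climate(seed = 19)
  sim <- generate_population(climate, pcfg, seed = 20)
  est <- fit_yearly_selection(sim$records, "fledglings")
  est <- est[est$flag == "ok", ]
  z <- mean(est$slope) / (sd(est$slope) / sqrt(nrow(est)))
  expect_lt(abs(z), 3)
})

test_that("the pipeline recovers the planted lay-tracking slope", {
  covered <- 0L
  ests <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_dataset("baseline", seed = 700 + s)
    first <- sim$records[sim$records$first_attempt, ]
    med <- do.call(rbind, lapply(split(first, first$year), function(d) {
      data.frame(year = d$year[1],
                 lay_doy = lower_median(as.POSIXlt(d$lay_date)$yday + 1))
    }))
    cand <- evaluate_candidate(sim$climate, med, 3, 200)
    ests[s] <- cand$slope
    covered <- covered + (abs(cand$slope - 0.424) <= 2 * cand$slope_se)
  }
  expect_gte(covered, 4L)
  expect_lt(abs(mean(ests) - 0.424), 0.1)
})

test_that("the mismatch scenario delays breeding in thermal terms over time", {
  trends <- sapply(1:4, function(s) {
    sim <- simulate_dataset("mismatch_trend", seed = 900 + s)
    ind <- list(t_base = 3, dates = sim$annual[, c("year", "spring_doy")])
    an <- annual_matching(sim$records, sim$climate, ind)
    coef(lm(match_median_ts_hatch ~ year, an))[2]
  })
  expect_gt(mean(trends), 0)
})
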