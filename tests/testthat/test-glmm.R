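gauss_spec <- model_spec("weight", "gaussian", c("year_c", "nestling_age"),
                         c("year", "territory", "female"), "year_c")

test_that("model specs validate their structure and read from YAML", {
  expect_error(model_spec("y", "gaussian", "x", "g", focal = "z"),
               "focal")
  expect_error(model_spec("y", "gaussian", "x", character(), "x"),
               "non-empty")
  expect_error(model_spec("y", "gamma", "x", "g", "x"))
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(response = "weight", family = "gaussian",
                        fixed = list("year_c", "nestling_age"),
                        random = list("year", "territory"),
                        focal = "year_c"), f)
  sp <- read_model_spec_yaml(f)
  expect_s3_class(sp, "model_spec")
  expect_equal(sp$fixed, c("year_c", "nestling_age"))
})

test_that("with zero random-effect variance the GLMM reduces to the GLM", {
  set.seed(71)
  n <- 600
  d <- data.frame(x = rnorm(n), g1 = factor(sample(12, n, TRUE)),
                  g2 = factor(sample(15, n, TRUE)))
  d$y_gauss <- 1 + 0.5 * d$x + rnorm(n)
  d$y_pois <- rpois(n, exp(0.3 + 0.4 * d$x))

  sp_g <- model_spec("y_gauss", "gaussian", "x", c("g1", "g2"), "x")
  fit_g <- fit_glmm(d, sp_g)
  ref_g <- lm(y_gauss ~ x, d)
  expect_lt(max(abs(fit_g$coefficients$estimate - coef(ref_g))), 1e-4)
  expect_true(fit_g$boundary)

  sp_p <- model_spec("y_pois", "poisson", "x", c("g1", "g2"), "x")
  fit_p <- fit_glmm(d, sp_p)
  ref_p <- glm(y_pois ~ x, poisson, d)
  expect_lt(max(abs(fit_p$coefficients$estimate - coef(ref_p))), 1e-4)

  expect_error(fit_glmm(d[d$g1 == "1", ], sp_g), "< 2 levels")
})

test_that("Gaussian fits recover planted effects and report drop-one LRTs", {
  d <- sim_gauss_crossed(seed = 81)
  fit <- fit_glmm(d, gauss_spec)
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "year_c"] - (-0.130)),
            3 * cf$se[cf$term == "year_c"])
  expect_lt(abs(cf$estimate[cf$term == "nestling_age"] - 2.213),
            3 * cf$se[cf$term == "nestling_age"])
  # the LRT identity chisq = 2 * delta_loglik holds on every reported row
  expect_equal(fit$term_tests$chisq, 2 * fit$term_tests$delta_loglik)
  expect_true(all(fit$term_tests$df == 1L))
  # random variances estimated for all three crossed groupings
  expect_named(fit$random_variances, c("female", "territory", "year"),
               ignore.order = TRUE)
  expect_false(fit$boundary)
})

test_that("lrt() agrees with independently fitted nested models", {
  d <- sim_gauss_crossed(seed = 82, n = 800)
  full <- fit_glmm(d, gauss_spec)
  red_spec <- model_spec("weight", "gaussian", "nestling_age",
                         c("year", "territory", "female"), "nestling_age")
  red <- fit_glmm(d, red_spec)
  out <- lrt(full, red)
  expect_equal(out$chisq, 2 * out$delta_loglik)
  expect_equal(out$df, 1L)
  # matches the drop-one table computed inside the full fit
  row <- full$term_tests[full$term_tests$term == "year_c", ]
  expect_equal(out$chisq, row$chisq, tolerance = 1e-6)
  # adding a covariate never decreases the ML log-likelihood
  expect_gte(full$loglik, red$loglik - 1e-8)
  # identical models: chisq 0, p 1
  same <- lrt(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # non-nested or different data are refused
  other_spec <- model_spec("weight", "gaussian", "year_c",
                           c("year", "territory", "female"), "year_c")
  other <- fit_glmm(d, other_spec)
  expect_error(lrt(other, red), "not nested")
  half <- fit_glmm(d[1:400, ], gauss_spec)
  expect_error(lrt(full, half), "different data")
})

test_that("Poisson fits recover a planted log-scale year trend", {
  set.seed(83)
  n <- 1000
  year <- sample(20, n, replace = TRUE)
  terr <- sample(25, n, replace = TRUE)
  re_y <- rnorm(20, 0, 0.15)
  re_t <- rnorm(25, 0, 0.15)
  d <- data.frame(y = rpois(n, exp(0.9 - 0.082 * (year - 1) +
                                     re_y[year] + re_t[terr])),
                  year_c = year - 1, year = factor(year),
                  territory = factor(terr))
  sp <- model_spec("y", "poisson", "year_c", c("year", "territory"), "year_c")
  fit <- fit_glmm(d, sp)
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "year_c"] - (-0.082)),
            3 * cf$se[cf$term == "year_c"])
  # Wald z p-values for non-Gaussian fixed effects
  expect_equal(cf$p, 2 * pnorm(-abs(cf$stat)))
})

test_that("marginal and conditional R2 follow the variance partition", {
  set.seed(84)
  # planted partition fixed:year:residual = 4:1:5
  n <- 4000
  year <- sample(40, n, replace = TRUE)
  re_y <- rnorm(40, 0, 1)
  x <- rnorm(n, 0, 2)
  d <- data.frame(y = x + re_y[year] + rnorm(n, 0, sqrt(5)),
                  x = x, year = factor(year))
  fit <- fit_glmm(d, model_spec("y", "gaussian", "x", "year", "x"))
  expect_lt(abs(fit$r2_marginal - 0.4), 0.05)
  expect_lt(abs(fit$r2_conditional - 0.5), 0.05)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)

  # without random variance the Gaussian R2 equals the classical R2
  d0 <- data.frame(y = x + rnorm(n, 0, sqrt(5)), x = x,
                   year = factor(year))
  fit0 <- fit_glmm(d0, model_spec("y", "gaussian", "x", "year", "x"))
  r2_lm <- summary(lm(y ~ x, d0))$r.squared
  expect_equal(fit0$r2_marginal, r2_lm, tolerance = 0.02)
  expect_equal(fit0$r2_marginal, fit0$r2_conditional, tolerance = 0.02)

  # no fixed-effect signal: marginal R2 near zero
  dn <- data.frame(y = re_y[year] + rnorm(n), x = rnorm(n),
                   year = factor(year))
  fitn <- fit_glmm(dn, model_spec("y", "gaussian", "x", "year", "x"))
  expect_lt(fitn$r2_marginal, 0.01)
})

test_that("bootstrap bands are reproducible, ordered, and collapse at B = 1", {
  d <- sim_gauss_crossed(seed = 85, n = 400, n_years = 10, n_terr = 10,
                         n_ind = 40)
  fit <- fit_glmm(d, gauss_spec)
  b1 <- bootstrap_predictions(fit, n_boot = 15, seed = 99)
  b2 <- bootstrap_predictions(fit, n_boot = 15, seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$median & b1$median <= b1$upper))
  b3 <- bootstrap_predictions(fit, n_boot = 1, seed = 99)
  expect_equal(b3$lower, b3$median)
  expect_equal(b3$upper, b3$median)
  grid <- c(0, 5, 10)
  b4 <- bootstrap_predictions(fit, grid = grid, n_boot = 5, seed = 1)
  expect_equal(b4$grid, grid)
})
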