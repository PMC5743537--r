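#' Specify a random-intercept GLMM
#'
#' @param response response column name (a demographic rate or nestling
#'   weight).
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param fixed ordered character vector of fixed-effect column names; must
#'   contain `focal`.
#' @param random non-empty character vector of grouping columns for random
#'   intercepts (typically year, territory and the individual id).
#' @param focal the focal predictor (e.g. `"year_c"` for trend models or
#'   `"median_ts"` for matching models).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response, family, fixed, random, focal) {
  family <- match.arg(family, c("gaussian", "binomial", "poisson"))
  if (!focal %in% fixed) stop("model_spec(): focal must be in fixed", call. = FALSE)
  if (length(random) < 1L) stop("model_spec(): random must be non-empty", call. = FALSE)
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, focal = focal),
            class = "model_spec")
}

#' Read a model spec from YAML
#'
#' Expected keys: `response`, `family`, `fixed` (list), `random` (list),
#' `focal`.
#' @param path YAML file.
#' @return a [model_spec()].
#' @export
read_model_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  model_spec(y$response, y$family, unlist(y$fixed), unlist(y$random), y$focal)
}

spec_formula <- function(spec) {
  stats::as.formula(paste(
    spec$response, "~", paste(spec$fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")))
}

#' Fit a crossed random-intercept GLMM
#'
#' Gaussian responses are fitted by `lme4::lmer` (maximum likelihood by
#' default, so that likelihood-ratio tests on fixed effects are valid;
#' `reml = TRUE` available for variance reporting); binomial and Poisson
#' responses by `lme4::glmer` with the Laplace approximation. For Gaussian
#' fits each fixed term is additionally tested by a drop-one likelihood-
#' ratio test (the `term_tests` table), mirroring how nestling-weight models
#' are reported; non-Gaussian fits report Wald z p-values.
#'
#' @param data data frame covering the spec's columns.
#' @param spec a [model_spec()].
#' @param reml use REML for Gaussian fits (disables term LRTs).
#' @param term_lrt compute drop-one LRTs per fixed term (default: Gaussian
#'   ML fits only).
#' @return list of class `glmm_fit`: the underlying `model`, `spec`,
#'   `coefficients` table (term, estimate, se, stat, p), `random_variances`,
#'   `loglik`, `n`, `term_tests` (term, delta_loglik, chisq, df, p; Gaussian
#'   ML only), `r2_marginal`, `r2_conditional`, `boundary` (singular-fit
#'   flag).
#' @export
fit_glmm <- function(data, spec, reml = FALSE,
                     term_lrt = identical(spec$family, "gaussian") && !reml) {
  stopifnot(inherits(spec, "model_spec"))
  for (g in spec$random) {
    if (length(unique(data[[g]])) < 2L) {
      stop("fit_glmm(): grouping factor '", g, "' has < 2 levels", call. = FALSE)
    }
  }
  fml <- spec_formula(spec)
  m <- fit_lme4(fml, data, spec$family, reml)
  msgs <- unlist(m@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs))) {
    stop("fit_glmm(): optimizer failed to converge: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  sm <- summary(m)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      stat = sm[, 3L], row.names = NULL,
                      stringsAsFactors = FALSE)
  coefs$p <- if (spec$family == "gaussian") NA_real_
             else 2 * stats::pnorm(-abs(coefs$stat))
  vc <- lme4::VarCorr(m)
  rv <- vapply(vc, function(v) v[1L, 1L], numeric(1))
  tt <- NULL
  if (term_lrt) {
    tt <- do.call(rbind, lapply(spec$fixed, function(tm) {
      # marginal gradient-check warnings on reduced fits are routine
      red <- suppressWarnings(drop_term_fit(data, spec, tm, reml))
      d_ll <- as.numeric(stats::logLik(m)) - as.numeric(stats::logLik(red))
      df <- attr(stats::logLik(m), "df") - attr(stats::logLik(red), "df")
      data.frame(term = tm, delta_loglik = d_ll, chisq = 2 * d_ll, df = df,
                 p = stats::pchisq(2 * d_ll, df, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
    # fill term p-values from the LRTs where terms map 1:1 to coefficients
    i <- match(coefs$term, tt$term)
    coefs$p[!is.na(i)] <- tt$p[i[!is.na(i)]]
  }
  r2 <- r2_nakagawa_internal(m, spec$family)
  structure(
    list(model = m, spec = spec, coefficients = coefs, random_variances = rv,
         loglik = as.numeric(stats::logLik(m)), n = stats::nobs(m),
         term_tests = tt, r2_marginal = r2[["marginal"]],
         r2_conditional = r2[["conditional"]],
         boundary = lme4::isSingular(m)),
    class = "glmm_fit"
  )
}

not_converged <- function(m) {
  any(grepl("failed to converge", unlist(m@optinfo$conv$lme4$messages)))
}

# fit with bobyqa; on a failed convergence check, restart once from the
# first optimum with Nelder-Mead (the standard lme4 remedy) before giving up
fit_lme4 <- function(fml, data, family, reml = FALSE) {
  if (family == "gaussian") {
    ctrl <- function(opt) lme4::lmerControl(optimizer = opt,
                                            check.conv.singular = "ignore")
    m <- lme4::lmer(fml, data = data, REML = reml, control = ctrl("bobyqa"))
    if (not_converged(m)) {
      m <- suppressWarnings(
        lme4::lmer(fml, data = data, REML = reml,
                   start = lme4::getME(m, "theta"),
                   control = ctrl("Nelder_Mead")))
    }
  } else {
    fam <- if (family == "binomial") stats::binomial() else stats::poisson()
    ctrl <- function(opt) lme4::glmerControl(optimizer = opt,
                                             optCtrl = list(maxfun = 1e5),
                                             check.conv.singular = "ignore")
    m <- lme4::glmer(fml, data = data, family = fam, control = ctrl("bobyqa"))
    if (not_converged(m)) {
      m <- suppressWarnings(
        lme4::glmer(fml, data = data, family = fam,
                    start = list(theta = lme4::getME(m, "theta"),
                                 fixef = lme4::fixef(m)),
                    control = ctrl("Nelder_Mead")))
    }
  }
  m
}

drop_term_fit <- function(data, spec, term, reml = FALSE) {
  fixed <- setdiff(spec$fixed, term)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(
    spec$response, "~", rhs, "+",
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")))
  fit_lme4(fml, data, spec$family, reml)
}

#' Likelihood-ratio test between two nested GLMM fits
#'
#' @param full,reduced `glmm_fit` objects fitted by maximum likelihood to the
#'   same data, with the reduced model's fixed effects a subset of the
#'   full model's.
#' @return list: `delta_loglik`, `chisq` (= 2 x delta_loglik), `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "glmm_fit"), inherits(reduced, "glmm_fit"))
  if (full$n != reduced$n) stop("lrt(): models fitted to different data", call. = FALSE)
  if (!all(reduced$spec$fixed %in% full$spec$fixed) ||
      !all(reduced$spec$random %in% full$spec$random)) {
    stop("lrt(): models are not nested", call. = FALSE)
  }
  df <- attr(stats::logLik(full$model), "df") -
    attr(stats::logLik(reduced$model), "df")
  if (df < 0L) stop("lrt(): reduced model has more parameters", call. = FALSE)
  d_ll <- full$loglik - reduced$loglik
  chisq <- 2 * d_ll
  list(delta_loglik = d_ll, chisq = chisq, df = df,
       p = if (df == 0L) 1 else stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Marginal and conditional R-squared for a GLMM
#'
#' Variance-partition R-squared: marginal = fixed-effect variance over the
#' total (fixed + random-intercept + distribution-specific) variance on the
#' link scale; conditional adds the random-intercept variance to the
#' numerator. Distribution-specific variance: residual variance (Gaussian),
#' pi^2/3 (binomial, logit link), trigamma(lambda) with lambda =
#' exp(mean linear predictor + half the random-effect variance) (Poisson,
#' log link).
#'
#' @param fit a `glmm_fit` (or a fitted `merMod` plus `family`).
#' @param family response family; taken from the spec when `fit` is a
#'   `glmm_fit`.
#' @return named numeric vector `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(fit, family = NULL) {
  if (inherits(fit, "glmm_fit")) {
    r2_nakagawa_internal(fit$model, fit$spec$family)
  } else {
    r2_nakagawa_internal(fit, family)
  }
}

r2_nakagawa_internal <- function(m, family) {
  eta_fixed <- as.vector(lme4::getME(m, "X") %*% lme4::fixef(m))
  var_f <- stats::var(eta_fixed)
  var_r <- sum(vapply(lme4::VarCorr(m), function(v) v[1L, 1L], numeric(1)))
  var_d <- switch(family,
    gaussian = stats::sigma(m)^2,
    binomial = pi^2 / 3,
    poisson = {
      lambda <- exp(mean(eta_fixed) + var_r / 2)
      trigamma(lambda)
    })
  tot <- var_f + var_r + var_d
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Parametric-bootstrap prediction band for the focal predictor
#'
#' For each bootstrap replicate: draw fixed effects from their asymptotic
#' normal distribution, simulate a response from the model with those
#' coefficients (random effects and residuals redrawn from the fitted
#' variances), refit, and predict at the grid of focal values with all other
#' covariates at reference values (numeric covariates at their mean, factors
#' at their most frequent level) and random effects at zero. The band is the
#' pointwise 2.5/50/97.5 percentile of the replicate predictions, on the
#' response scale.
#'
#' @param fit a converged `glmm_fit`.
#' @param grid focal values to predict at; default 25 points spanning the
#'   observed range.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed; the band is reproducible given a seed.
#' @param max_fail_frac abort if more than this fraction of refits fail
#'   (default 0.2).
#' @return data frame of class `bootstrap_band`: `grid`, `lower`, `median`,
#'   `upper`; attributes `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_predictions <- function(fit, grid = NULL, n_boot = 1000L, seed = 1L,
                                  max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "glmm_fit"))
  set.seed(seed)
  m <- fit$model
  focal <- fit$spec$focal
  mf <- m@frame
  if (is.null(grid)) {
    rng <- range(mf[[focal]])
    grid <- seq(rng[1L], rng[2L], length.out = 25L)
  }
  newdata <- reference_row(mf, fit$spec)
  newdata <- newdata[rep(1L, length(grid)), , drop = FALSE]
  newdata[[focal]] <- grid
  beta <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  theta <- lme4::getME(m, "theta")
  preds <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    beta_b <- MASS::mvrnorm(1L, beta, V)
    np <- list(beta = beta_b, theta = theta)
    if (fit$spec$family == "gaussian") np$sigma <- stats::sigma(m)
    y_b <- suppressWarnings(
      stats::simulate(m, nsim = 1L, newparams = np)[[1L]])
    pred_b <- tryCatch(
      suppressWarnings(suppressMessages({
        refit_b <- lme4::refit(m, y_b)
        stats::predict(refit_b, newdata = newdata, re.form = NA,
                       type = "response")
      })),
      error = function(e) NULL)
    if (is.null(pred_b)) {
      n_failed <- n_failed + 1L
      next
    }
    preds[b, ] <- pred_b
  }
  if (n_failed > max_fail_frac * n_boot) {
    stop("bootstrap_predictions(): ", n_failed, "/", n_boot, " refits failed",
         call. = FALSE)
  }
  q <- apply(preds, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             na.rm = TRUE)
  out <- data.frame(grid = grid, lower = q[1L, ], median = q[2L, ],
                    upper = q[3L, ])
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_band", "data.frame")
  out
}

# covariate reference row: numeric at mean, factors/chars at modal level
reference_row <- function(mf, spec) {
  vars <- spec$fixed
  row <- lapply(vars, function(v) {
    x <- mf[[v]]
    if (is.numeric(x)) mean(x)
    else if (is.factor(x)) factor(names(which.max(table(x))), levels = levels(x))
    else names(which.max(table(x)))
  })
  names(row) <- vars
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s (%s), n = %d, logLik = %.1f, R2m = %.3f, R2c = %.3f%s\n",
              x$spec$response, x$spec$family, x$n, x$loglik,
              x$r2_marginal, x$r2_conditional,
              if (x$boundary) " [boundary fit]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Write a fit report (CSV of terms + JSON of variances/likelihood/R2)
#'
#' @param fit a `glmm_fit`.
#' @param path_prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param provenance optional provenance string for the CSV header.
#' @return invisibly, the two paths.
#' @export
write_fit_report <- function(fit, path_prefix, provenance = NULL) {
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  write_csv_with_header(fit$coefficients, csv, provenance)
  jsonlite::write_json(
    list(response = fit$spec$response, family = fit$spec$family,
         random_variances = as.list(fit$random_variances),
         loglik = fit$loglik, n = fit$n,
         r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
         boundary = fit$boundary, provenance = provenance),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
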