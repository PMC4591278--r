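test_that("explained deviance is the percentage reduction over the null", {
  expect_equal(explained_deviance(100, 100), 0)
  expect_equal(explained_deviance(100, 0), 100)
  expect_equal(explained_deviance(100, 46), 54)
  expect_error(explained_deviance(100, 120))
  expect_error(explained_deviance(0, 0))
})

test_that("kappa matches hand-computed confusion tables", {
  expect_equal(kappa_statistic(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  # TP = 40, TN = 40, FP = 10, FN = 10: p_o = 0.8, p_e = 0.5, kappa = 0.6
  obs <- rep(c(TRUE, FALSE), each = 50)
  pred <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  expect_equal(kappa_statistic(obs, pred), 0.6)
  # chance-only agreement: a constant prediction scores exactly zero
  expect_equal(kappa_statistic(obs, rep(TRUE, 100)), 0)
  expect_error(kappa_statistic(rep(TRUE, 4), rep(TRUE, 4)), "both classes")
})

test_that("AUC follows the rank (Mann-Whitney) formulation with half ties", {
  expect_equal(auc_statistic(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1)), 1)
  expect_equal(auc_statistic(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4)), 0.5)
  # exhaustive pair counting: 3 concordant pairs of 4
  expect_equal(auc_statistic(c(TRUE, TRUE, FALSE, FALSE),
                             c(0.9, 0.8, 0.85, 0.1)), 0.75)
  expect_equal(auc_statistic(c(TRUE, FALSE), c(0.7, 0.7)), 0.5)
  expect_error(auc_statistic(c(TRUE, TRUE), c(0.5, 0.6)), "both classes")
})

test_that("kappa and AUC agree with brute-force oracles on random instances", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    obs <- c(TRUE, FALSE, runif(n - 2) < 0.5)   # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    pred <- scores >= runif(1)
    expect_equal(kappa_statistic(obs, pred), kappa_oracle(obs, pred))
    expect_equal(auc_statistic(obs, scores), auc_oracle(obs, scores))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  obs <- c(TRUE, FALSE, runif(48) < 0.4)
  scores <- runif(50)
  expect_equal(auc_statistic(obs, scores),
               as.numeric(pROC::auc(pROC::roc(obs, scores, quiet = TRUE))))
})

test_that("the kappa-maximizing threshold scans score midpoints", {
  expect_equal(best_threshold(c(TRUE, FALSE), c(0.9, 0.1)), 0.5)
  # perfectly separated scores: the smallest maximizing midpoint is returned
  obs <- c(rep(TRUE, 3), rep(FALSE, 3))
  sc <- c(0.9, 0.85, 0.7, 0.4, 0.3, 0.1)
  expect_equal(best_threshold(obs, sc), 0.55)
  th <- best_threshold(obs, sc)
  expect_equal(kappa_statistic(obs, sc >= th), 1)
  expect_error(best_threshold(rep(TRUE, 3), c(0.1, 0.5, 0.9)),
               "both classes")
  # exhaustive-scan oracle on random instances: no threshold does better
  set.seed(53)
  for (i in 1:20) {
    obs <- c(TRUE, FALSE, runif(18) < 0.5)
    sc <- round(runif(20), 2)
    th <- best_threshold(obs, sc)
    best_kappa <- kappa_statistic(obs, sc >= th)
    for (cand in seq(0, 1, by = 0.01)) {
      k <- kappa_statistic(obs, sc >= cand)
      if (!is.na(k)) expect_lte(k, best_kappa + 1e-12)
    }
  }
})

# shared synthetic SDM data: dome response to temperature, two pure-noise
# candidate predictors, log-normal surface areas
make_sdm_data <- function(n = 150, topt = 16, seed = 54) {
  set.seed(seed)
  temp <- runif(n, 4, 28)
  dome <- thermal_dome(temp, thermal_response(6, topt, 26))
  data.frame(
    presence = as.integer(runif(n) < dome),
    temperature = temp,
    surface_area = rlnorm(n, log(5000), 1),
    noise = rnorm(n))
}

test_that("the AIC search recovers the generating predictor and optimum", {
  dat <- make_sdm_data()
  fit <- fit_sdm(dat, c("temperature", "surface_area", "noise"), seed = 2)
  expect_true("temperature" %in% fit$predictors)
  expect_lte(length(fit$predictors), 3)
  # the selected model's AIC is minimal over every candidate subset
  expect_equal(fit$aic, min(fit$aic_table$aic, na.rm = TRUE))
  expect_equal(nrow(fit$aic_table), 7)  # all subsets of sizes 1-3
  # fitted thermal optimum close to the generating one
  expect_lt(abs(fitted_optimum(fit, "temperature") - 16), 2)
  # metrics live on their scales
  m <- fit$metrics
  expect_true(m$auc_cal >= 0.5 && m$auc_cal <= 1)
  expect_true(m$explained_deviance >= 0 && m$explained_deviance <= 100)
  expect_true(fit$threshold >= 0 && fit$threshold <= 1)
  expect_lte(fit$deviance, fit$null_deviance)
})

test_that("a single candidate degenerates to one fit, returned regardless", {
  dat <- make_sdm_data(n = 60)
  fit <- fit_sdm(dat, "temperature", seed = 3)
  expect_equal(fit$predictors, "temperature")
  expect_equal(nrow(fit$aic_table), 1)
})

test_that("perfectly separable data reach kappa 1 at the best threshold", {
  set.seed(55)
  x <- c(runif(20, 0, 1), runif(20, 3, 4))
  dat <- data.frame(presence = rep(c(0L, 1L), each = 20), x = x)
  fit <- suppressWarnings(fit_sdm(dat, "x", seed = 4, log_transform = NULL))
  expect_equal(fit$metrics$kappa_cal, 1)
  expect_equal(fit$metrics$kappa_val, 1)
  expect_equal(fit$metrics$auc_cal, 1)
})

test_that("the calibration split is stratified and seeded", {
  dat <- make_sdm_data(n = 100)
  fit1 <- fit_sdm(dat, "temperature", seed = 7)
  fit2 <- fit_sdm(dat, "temperature", seed = 7)
  expect_identical(fit1$calibration_rows, fit2$calibration_rows)
  fit3 <- fit_sdm(dat, "temperature", seed = 8)
  expect_false(identical(fit1$calibration_rows, fit3$calibration_rows))
  cal_prev <- mean(dat$presence[fit1$calibration_rows])
  expect_equal(cal_prev, mean(dat$presence), tolerance = 0.05)
  expect_equal(length(fit1$calibration_rows), round(0.75 * sum(dat$presence)) +
                 round(0.75 * sum(!dat$presence)))
})

test_that("projection reproduces fitted values and flags extrapolation", {
  dat <- make_sdm_data(n = 120)
  fit <- fit_sdm(dat, c("temperature", "surface_area"), seed = 5)
  cal <- dat[fit$calibration_rows, ]
  proj <- project_sdm(fit, cal)
  inside <- as.numeric(stats::predict(fit$model, {
    d <- cal; d$surface_area <- log(d$surface_area); d
  }, type = "response"))
  expect_equal(proj$p_suit, inside, tolerance = 1e-12)
  expect_false(any(proj$extrapolated))
  # shifting a predictor far past its fitted range flags extrapolation and,
  # on a dome response, lowers suitability below the optimum's
  far <- cal
  far$temperature <- far$temperature + 40
  proj_far <- project_sdm(fit, far)
  expect_true(all(proj_far$extrapolated))
  expect_true(all(proj_far$p_suit >= 0 & proj_far$p_suit <= 1))
  # empty input, empty output
  expect_equal(nrow(project_sdm(fit, dat[0, ])), 0)
})
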