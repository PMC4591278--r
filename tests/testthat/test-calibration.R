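test_that("the distribution log-likelihood statistic matches its closed form", {
  # perfect predictions: every term is log(1.001)
  expect_equal(ss_presence_loglik(c(1, 1, 1, 0, 0),
                                  c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               5 * log(1.001))
  # worst-case presence term is log(delta)
  expect_equal(ss_presence_loglik(0, TRUE), log(0.001))
  # with delta = 0 and interior probabilities this is the Bernoulli
  # log-likelihood
  p <- c(0.3, 0.8, 0.6)
  obs <- c(FALSE, TRUE, TRUE)
  expect_equal(ss_presence_loglik(p, obs, delta = 0),
               sum(stats::dbinom(as.integer(obs), 1, p, log = TRUE)))
  # maximized exactly at p = 1 on presences and p = 0 on absences
  # (grid search over probability assignments on a small problem)
  obs2 <- c(TRUE, FALSE)
  grid <- seq(0, 1, by = 0.05)
  vals <- outer(grid, grid, Vectorize(function(a, b)
    ss_presence_loglik(c(a, b), obs2)))
  best <- which(vals == max(vals), arr.ind = TRUE)
  expect_equal(grid[best[1, 1]], 1)
  expect_equal(grid[best[1, 2]], 0)
})

test_that("the northern-limit statistic applies the 50-juvenile rule", {
  rec <- matrix(100, 10, 3)
  res <- fake_result(rec, latitudes = c(45, 53, 50))
  expect_equal(ss_northern_limit(res), 53)
  rec2 <- rec; rec2[, 2] <- 10                 # mid basin below threshold
  expect_equal(ss_northern_limit(fake_result(rec2, latitudes = c(45, 53, 50))),
               50)
  expect_equal(ss_northern_limit(fake_result(rec * 0,
                                             latitudes = c(45, 53, 50))),
               NA_real_)                       # undefined sentinel
  rec3 <- matrix(c(100, 10, 10), 10, 3, byrow = TRUE)
  expect_equal(ss_northern_limit(fake_result(rec3, latitudes = c(45, 53, 50))),
               45)                             # single populated basin
})

test_that("the spawner-age statistic sums squared deviations from five", {
  expect_equal(ss_spawner_age(c(5, 5, 5)), 0)
  expect_equal(ss_spawner_age(c(4, 6)), 2)
  expect_equal(ss_spawner_age(3), 4)
  expect_equal(ss_spawner_age(c(4, NA, 6)), 2)  # silent basins drop out
})

test_that("the complete two-level factorial design is full and orthogonal", {
  d2 <- factorial_design(list(a = c(0, 1), b = c(10, 20)))
  expect_equal(nrow(d2$values), 4L)
  expect_setequal(d2$values$a, c(0, 1))
  d3 <- factorial_design(list(a = c(0, 1), b = c(0, 1), c = c(0, 1)),
                         replicates = 10)
  expect_equal(nrow(d3$values), 8L)
  expect_equal(d3$replicates, 10L)
  # coded columns are balanced and mutually orthogonal
  G <- t(d3$coded) %*% d3$coded
  expect_equal(G, diag(8, 3), ignore_attr = TRUE)
  expect_equal(colSums(d3$coded), c(a = 0, b = 0, c = 0))
  expect_error(factorial_design(list(a = c(1, 0))), "min < max")
  expect_error(factorial_design(list(c(0, 1))), "named")
})

test_that("sensitivity indices match the contrast-sum ANOVA oracle", {
  d <- factorial_design(list(a = c(-1, 1), b = c(-1, 1)), replicates = 3)
  x <- d$coded
  set.seed(41)
  # pure main effect of one parameter
  y1 <- matrix(rep(3 * x[, "a"], 3), ncol = 3)
  s1 <- sensitivity_indices(d, y1)
  expect_equal(unname(s1$main), c(1, 0))
  expect_equal(s1$interaction["a", "b"], 0)
  # pure product interaction: no main effects at all
  y2 <- matrix(rep(x[, "a"] * x[, "b"], 3), ncol = 3)
  s2 <- sensitivity_indices(d, y2)
  expect_equal(unname(s2$main), c(0, 0))
  expect_equal(s2$interaction["a", "b"], 1)
  # mixed effects with replicate noise: agree with the oracle exactly
  y3 <- matrix(rep(2 * x[, "a"] + x[, "b"] + 0.5 * x[, "a"] * x[, "b"], 3),
               ncol = 3) + matrix(rnorm(12, 0, 0.3), ncol = 3)
  s3 <- sensitivity_indices(d, y3)
  o3 <- anova_shares_oracle(d$coded, y3)
  expect_equal(unname(s3$main), o3$main, tolerance = 1e-10)
  expect_equal(s3$interaction["a", "b"], o3$interaction[1, 2],
               tolerance = 1e-10)
  expect_true(s3$residual > 0)
  expect_equal(sum(s3$main) + s3$interaction["a", "b"] + s3$residual, 1,
               tolerance = 1e-10)
  # a constant response yields all-zero indices, not an error
  s4 <- sensitivity_indices(d, matrix(7, 4, 3))
  expect_equal(unname(s4$main), c(0, 0))
  expect_equal(s4$residual, 0)
})

test_that("a design can drive a simulator through evaluate_design", {
  d <- factorial_design(list(a = c(0, 1), b = c(0, 10)), replicates = 2)
  sim <- function(pars, seed) c(s1 = pars[["a"]] + pars[["b"]], s2 = seed %% 7)
  out <- evaluate_design(d, sim, seed = 1)
  expect_named(out, c("s1", "s2"))
  expect_equal(dim(out$s1), c(4L, 2L))
  expect_equal(out$s1[, 1], rowSums(d$values))
})

test_that("rejection ABC accepts the configured quantile and identifies", {
  # degenerate identification: the discrepancy vanishes only near the truth
  sim <- function(pars, seed) c(s = (pars[["x"]] - 0.3)^2 +
                                  (pars[["y"]] - 0.7)^2)
  res <- abc_calibrate(priors = list(x = c(0, 1), y = c(0, 1)),
                       targets = c(s = 0), simulator = sim,
                       n_draws = 1000, accept_rate = 0.1, seed = 9)
  expect_equal(res$n_accepted, 100L)          # exact quantile arithmetic
  expect_equal(nrow(res$accepted), 100L)
  expect_lt(abs(res$summaries$x[["mode"]] - 0.3), 0.15)
  expect_lt(abs(res$summaries$y[["mode"]] - 0.7), 0.15)
  expect_true(abc_contains(res, c(x = 0.3, y = 0.7)))
  # posterior width shrinks as acceptance tightens on the same table
  ref <- abc_reference_table(sim, list(x = c(0, 1), y = c(0, 1)),
                             n_draws = 2000, seed = 10)
  wide <- abc_calibrate(priors = list(x = c(0, 1), y = c(0, 1)),
                        targets = c(s = 0), reference = ref,
                        accept_rate = 0.5)
  tight <- abc_calibrate(priors = list(x = c(0, 1), y = c(0, 1)),
                         targets = c(s = 0), reference = ref,
                         accept_rate = 0.02)
  width <- function(r) diff(unname(stats::quantile(r$accepted$x,
                                                   c(0.025, 0.975))))
  expect_lt(width(tight), width(wide))
})

test_that("ABC treats undefined statistics as maximal discrepancy", {
  sim <- function(pars, seed)
    c(s1 = pars[["x"]],
      s2 = if (pars[["x"]] > 0.5) NA_real_ else pars[["x"]])
  res <- abc_calibrate(priors = list(x = c(0, 1)),
                       targets = c(s1 = 0.2, s2 = 0.2), simulator = sim,
                       n_draws = 400, accept_rate = 0.1, seed = 11)
  # draws with the undefined statistic are pushed out of the accepted set
  expect_true(all(res$accepted$x <= 0.5))
  expect_lt(abs(res$summaries$x[["mode"]] - 0.2), 0.2)
})

test_that("posterior sampling and failure modes behave", {
  sim <- function(pars, seed) c(s = pars[["x"]])
  res <- abc_calibrate(priors = list(x = c(0, 1)), targets = c(s = 0.5),
                       simulator = sim, n_draws = 200, accept_rate = 0.1,
                       seed = 12)
  draws <- abc_posterior_sample(res, n = 50, seed = 1)
  expect_equal(nrow(draws), 50L)
  expect_true(all(draws$x >= 0 & draws$x <= 1))
  expect_error(abc_calibrate(priors = list(x = c(0, 1)),
                             targets = c(s = 0.5), simulator = sim,
                             n_draws = 10, accept_rate = 2, seed = 1),
               "fewer simulations")
  expect_error(abc_calibrate(priors = list(x = c(0, 1)),
                             targets = c(zz = 1), simulator = sim,
                             n_draws = 10, seed = 1),
               "named after")
})
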