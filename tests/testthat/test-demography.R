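test_that("thermal dome hits its analytic anchors", {
  resp <- thermal_response(3, 17, 26)
  expect_equal(thermal_dome(17, resp), 1)
  expect_equal(thermal_dome(3, resp), 0)
  expect_equal(thermal_dome(26, resp), 0)
  expect_equal(thermal_dome(10, resp), 112 / 161)  # direct evaluation
  expect_equal(thermal_dome(-5, resp), 0)
  expect_equal(thermal_dome(40, resp), 0)
})

test_that("thermal dome is bounded, continuous at the bounds and unimodal", {
  set.seed(21)
  for (i in 1:10) {
    tmin <- runif(1, 0, 10)
    topt <- tmin + runif(1, 1, 10)
    tmax <- topt + runif(1, 1, 10)
    resp <- thermal_response(tmin, topt, tmax)
    grid <- seq(tmin - 2, tmax + 2, length.out = 400)
    v <- thermal_dome(grid, resp)
    expect_true(all(v >= 0 & v <= 1))
    expect_lt(thermal_dome(tmin + 1e-6, resp), 1e-4)  # continuous clamp
    expect_lt(thermal_dome(tmax - 1e-6, resp), 1e-4)
    inside <- grid > tmin & grid < tmax
    expect_equal(grid[inside][which.max(v[inside])], topt, tolerance = 0.05)
    # unimodal: increasing left of the optimum, decreasing right of it
    left <- v[inside & grid <= topt]
    right <- v[inside & grid >= topt]
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
  }
})

test_that("Allee multiplier is anchored at S95 and S50 and increasing", {
  # eta = 2.4, theta = 2, wa = 1000: S95 = 2400, S50 = 1200
  expect_equal(allee_multiplier(2400, 1000, 2.4, 2), 0.95)
  expect_equal(effective_spawners(2400, 1000, 2.4, 2), 2280)
  expect_equal(allee_multiplier(1200, 1000, 2.4, 2), 0.5)
  expect_equal(effective_spawners(1200, 1000, 2.4, 2), 600)
  expect_equal(allee_multiplier(0, 1000, 2.4, 2), 1 / (1 + 19))
  set.seed(22)
  for (i in 1:10) {
    eta <- runif(1, 0.5, 5); theta <- runif(1, 1.2, 3)
    wa <- runif(1, 100, 1e5)
    expect_equal(allee_multiplier(eta * wa, wa, eta, theta), 0.95)
    expect_equal(allee_multiplier(eta * wa / theta, wa, eta, theta), 0.5)
    s <- seq(0, 3 * eta * wa, length.out = 200)
    m <- allee_multiplier(s, wa, eta, theta)
    expect_true(all(diff(m) > 0))          # strictly increasing
    expect_true(all(m > 0 & m < 1))
  }
})

test_that("recruitment honours its zeros, asymptote and low-density slope", {
  p <- species_parameters(sigma_rep = 0)
  wa <- 1000
  expect_equal(recruitment(0, wa, 20, p), 0)
  expect_equal(recruitment(1e4, wa, p$tmin_rep, p), 0)      # cold water
  expect_equal(recruitment(1e4, wa, p$tmin_rep - 3, p), 0)
  # Beverton-Holt asymptote: capacity scales with drainage area
  expect_equal(recruitment(1e12, wa, p$topt_rep, p),
               p$lambda_rec * wa * 1e6, tolerance = 1e-4)
  # monotone non-decreasing in the stock
  s <- seq(0, 5e4, length.out = 100)
  r <- vapply(s, recruitment, numeric(1), wa = wa, t_water = 18, params = p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= p$lambda_rec * wa * 1e6))
  # slope of the kernel at the origin = fecundity x egg survival
  # (difference quotient on the Beverton-Holt component, Allee factored out)
  surv <- p$surv_opt_rep * thermal_dome(18, thermal_rep(p))
  h <- 1e-6
  kernel_slope <- shadrange:::beverton_holt(
    h, p$lambda_rec * wa * 1e6,
    p$lambda_rec * wa * 1e6 / (p$fecundity * surv)) / h
  expect_equal(kernel_slope, p$fecundity * surv, tolerance = 1e-6)
})

test_that("stochastic recruitment is mean-corrected", {
  p <- species_parameters(sigma_rep = 0.4)
  det <- recruitment(5000, 800, 19, species_parameters(sigma_rep = 0))
  set.seed(23)
  draws <- replicate(4000, recruitment(5000, 800, 19, p))
  expect_gt(stats::sd(draws), 0)
  expect_equal(mean(draws), det, tolerance = 0.02)
})

test_that("growth follows the seasonal von Bertalanffy increment", {
  p <- species_parameters(k_opt_grow = 0.3, sigma_dl = 0)
  expect_equal(grow(2, 17, p), 2 + 58 * (1 - exp(-0.3)))  # ~17.03 cm
  expect_equal(grow(30, p$tmin_grow - 1, p), 30)          # null growth cold
  expect_equal(grow(30, p$tmax_grow + 1, p), 30)          # null growth warm
  expect_equal(grow(p$l_inf, 17, p), p$l_inf)             # asymptote
  # repeated growth converges monotonically to l_inf from below
  l <- 2
  path <- numeric(100)
  for (i in 1:100) { l <- grow(l, 17, p); path[i] <- l }
  expect_true(all(diff(path) >= 0))
  expect_true(all(path <= p$l_inf))
  expect_equal(path[100], p$l_inf, tolerance = 1e-6)
})

test_that("stochastic growth never shrinks fish nor exceeds the asymptote", {
  p <- species_parameters(sigma_dl = 0.5)
  set.seed(24)
  l <- rep(2, 500)
  for (i in 1:60) {
    l2 <- grow(l, 16, p)
    expect_true(all(l2 >= l))
    expect_true(all(l2 <= p$l_inf))
    l <- l2
  }
})

test_that("survival probabilities follow their exponential forms", {
  expect_equal(sea_survival_probability(species_parameters(z_sea = 0)), 1)
  expect_equal(sea_survival_probability(species_parameters(z_sea = 0.4)),
               exp(-0.1))
  expect_equal(sea_survival_probability(species_parameters(z_sea = 0.6)),
               exp(-0.15))
  p <- species_parameters(surv_opt_riv = 1, h_riv = 0)
  expect_equal(river_survival_probability(p$topt_surv_riv, p), 1)
  expect_equal(river_survival_probability(p$tmin_surv_riv, p), 0)
  expect_equal(river_survival_probability(p$tmin_surv_riv - 2, p), 0)
  p2 <- species_parameters(surv_opt_riv = 1, h_riv = 0.2)
  expect_equal(river_survival_probability(p2$topt_surv_riv, p2), exp(-0.05))
  # all survival probabilities live in [0, 1] across the thermal range
  grid <- seq(-5, 40, length.out = 200)
  v <- river_survival_probability(grid, species_parameters())
  expect_true(all(v >= 0 & v <= 1))
})

test_that("post-spawning survival scales cohort weight by the iteroparity rate", {
  p <- species_parameters(sp_sp = 0.1)
  expect_equal(post_spawning_survival(1000, p), 100)
  expect_equal(post_spawning_survival(1000, species_parameters(sp_sp = 0)), 0)
  expect_equal(post_spawning_survival(1000, species_parameters(sp_sp = 1)),
               1000)
  set.seed(25)
  draws <- replicate(2000, post_spawning_survival(100, p, stochastic = TRUE))
  expect_equal(mean(draws), 10, tolerance = 0.1)
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("maturity is an inclusive length threshold", {
  p <- species_parameters(l_mat = 40)
  expect_false(is_mature(35.9, species_parameters(l_mat = 36)))
  expect_true(is_mature(40, p))
  expect_true(is_mature(44.1, species_parameters(l_mat = 44)))
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(species_parameters(theta = 1), "theta")
  expect_error(species_parameters(p_hom = 1.2), "probability")
  expect_error(species_parameters(tmin_rep = 30), "tmin < topt < tmax")
  expect_error(species_parameters(nonsense = 1), "unknown")
  expect_error(species_parameters(l_inf = 1), "l_inf")
})
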