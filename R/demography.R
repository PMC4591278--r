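#' Dome-shaped thermal performance
#'
#' Evaluates the dome response
#' \deqn{\kappa(T) = \frac{(T - T_{min})(T - T_{max})}
#'   {(T - T_{min})(T - T_{max}) - (T - T_{opt})^2}}
#' which equals 1 at the optimum, falls continuously to 0 at both bounds and
#' is 0 outside the window. Used for egg-to-recruit survival, growth and
#' river survival, each with its own temperature triplet.
#'
#' @param t water temperature(s), degC (vectorized)
#' @param resp a [thermal_response()]
#' @return performance fraction(s) in \[0, 1\]
#' @examples
#' thermal_dome(17, thermal_response(3, 17, 26))  # 1
#' thermal_dome(10, thermal_response(3, 17, 26))  # 112/161
#' @export
thermal_dome <- function(t, resp) {
  stopifnot(inherits(resp, "thermal_response"), is.numeric(t))
  num <- (t - resp$tmin) * (t - resp$tmax)
  den <- num - (t - resp$topt)^2
  out <- ifelse(t <= resp$tmin | t >= resp$tmax, 0, num / den)
  # den == 0 can only occur at the window bounds, already clamped above
  out[!is.finite(out)] <- 0
  out
}

#' Allee-effect multiplier on spawner numbers
#'
#' Logistic depensation on the spawner stock: the fraction of spawners that
#' effectively reproduce rises with stock size, reaching 0.5 at
#' `S50 = eta * wa / theta` and 0.95 at `S95 = eta * wa` (the `log(19)`
#' anchoring). Depensation is thereby scaled to the basin's drainage area
#' `wa` (km2): establishing a population from few colonists is harder in a
#' large basin.
#'
#' @param s spawner count(s) (vectorized)
#' @param wa basin surface area, km2
#' @param eta spawners per km2 at the 95\% point
#' @param theta ratio `S95 / S50` (> 1)
#' @return multiplier(s) in (0, 1)
#' @export
allee_multiplier <- function(s, wa, eta, theta) {
  stopifnot(wa > 0, eta > 0, theta > 1)
  s95 <- eta * wa
  s50 <- eta * wa / theta
  1 / (1 + exp(-log(19) * (s - s50) / (s95 - s50)))
}

#' @rdname allee_multiplier
#' @return `effective_spawners()`: the effective stock `s * multiplier`
#' @examples
#' effective_spawners(2400, wa = 1000, eta = 2.4, theta = 2)  # 2280
#' @export
effective_spawners <- function(s, wa, eta, theta) {
  stopifnot(all(s >= 0))
  s * allee_multiplier(s, wa, eta, theta)
}

# Beverton-Holt kernel on the effective stock. alpha is the asymptotic
# recruitment, beta the half-saturation stock; slope at the origin is
# alpha / beta.
beverton_holt <- function(s_eff, alpha, beta) {
  alpha * s_eff / (beta + s_eff)
}

# Beverton-Holt parameters reconstructed from the species parameters:
# capacity scales with drainage area (lambda_rec per m2, wa in km2) and the
# half-saturation constant is set so the density-independent slope equals
# fecundity x temperature-dependent egg-to-recruit survival. Isolated here
# so an alternative parameterization can be swapped in.
bh_parameters <- function(wa, egg_survival, params) {
  alpha <- params$lambda_rec * wa * 1e6
  beta <- if (egg_survival > 0) alpha / (params$fecundity * egg_survival)
          else Inf
  list(alpha = alpha, beta = beta)
}

#' Annual recruitment in a basin
#'
#' Number of recruits (juveniles aged `dt_rec`) produced by `s` spawners in a
#' basin of area `wa` at water temperature `t_water`. The deterministic
#' kernel is a Beverton-Holt relation on the Allee-corrected effective stock,
#' with asymptote `lambda_rec * wa * 1e6` and low-density slope
#' `fecundity * surv_opt_rep * thermal_dome(t_water)`. The realized value
#' multiplies the kernel by mean-corrected log-normal noise
#' (`exp(eps - sigma_rep^2 / 2)`, `eps ~ N(0, sigma_rep)`), so its
#' expectation equals the kernel. Zero spawners, or a temperature outside
#' the reproduction window, produce exactly zero recruits.
#'
#' @param s spawner count
#' @param wa basin surface area, km2
#' @param t_water water temperature during the reproduction season, degC
#' @param params a [species_parameters()]
#' @param stochastic draw the log-normal noise? (`FALSE` returns the kernel)
#' @return recruit count (non-negative scalar)
#' @export
recruitment <- function(s, wa, t_water, params, stochastic = TRUE) {
  stopifnot(s >= 0, wa > 0)
  surv <- params$surv_opt_rep * thermal_dome(t_water, thermal_rep(params))
  if (s == 0 || surv <= 0) return(0)
  bh <- bh_parameters(wa, surv, params)
  s_eff <- effective_spawners(s, wa, params$eta, params$theta)
  r <- beverton_holt(s_eff, bh$alpha, bh$beta)
  if (stochastic && params$sigma_rep > 0)
    r <- r * exp(stats::rnorm(1, 0, params$sigma_rep) - params$sigma_rep^2 / 2)
  r
}

#' Seasonal von Bertalanffy growth at sea
#'
#' One seasonal length increment
#' `(l_inf - length) * (1 - exp(-k_opt_grow * thermal_dome(t)))`,
#' where the dome uses the growth window. Outside the window growth is null.
#' With `stochastic = TRUE`, the increment carries multiplicative unit-mean
#' log-normal noise (sd `sigma_dl` on the log scale). Length never decreases
#' and never exceeds `l_inf`.
#'
#' @param length current fork length(s), cm (vectorized)
#' @param t_water water temperature, degC (scalar or same length)
#' @param params a [species_parameters()]
#' @param stochastic add log-normal noise to the increment?
#' @return updated length(s), cm
#' @examples
#' grow(2, 17, species_parameters(k_opt_grow = 0.3, sigma_dl = 0))
#' @export
grow <- function(length, t_water, params, stochastic = TRUE) {
  stopifnot(all(length >= 0))
  kappa <- params$k_opt_grow * thermal_dome(t_water, thermal_grow(params))
  dl <- (params$l_inf - length) * (1 - exp(-kappa))
  if (stochastic && params$sigma_dl > 0) {
    eps <- stats::rnorm(base::length(dl), 0, params$sigma_dl)
    dl <- dl * exp(eps - params$sigma_dl^2 / 2)
  }
  pmin(pmax(length + dl, length), params$l_inf)
}

#' Per-season survival probabilities
#'
#' At sea, survival over a quarter year under the fixed annual mortality
#' coefficient `z_sea`: `exp(-z_sea / 4)`. In river, the optimal annual
#' survival is modulated by the river thermal window, raised to the 1/4
#' power for a seasonal step, and multiplied by `exp(-h_riv / 4)` for any
#' additional (non-natural) mortality; it is zero outside the window.
#'
#' @param params a [species_parameters()]
#' @param t_water water temperature, degC (vectorized)
#' @return probability (or vector of probabilities) in \[0, 1\]
#' @examples
#' sea_survival_probability(species_parameters(z_sea = 0.4))  # exp(-0.1)
#' @export
sea_survival_probability <- function(params) {
  exp(-params$z_sea * 0.25)
}

#' @rdname sea_survival_probability
#' @export
river_survival_probability <- function(t_water, params) {
  dome <- thermal_dome(t_water, thermal_surv_riv(params))
  (params$surv_opt_riv * dome)^0.25 * exp(-params$h_riv * 0.25)
}

#' Post-spawning survival of a spawner cohort
#'
#' Applies the iteroparity rate `sp_sp` to the weight of a spawner
#' super-individual. By default the weight is scaled deterministically
#' (`weight * sp_sp`, the expected value); with `stochastic = TRUE` the
#' survivors are drawn binomially, which matters for small cohorts.
#'
#' @param weight cohort weight (number of fish, real-valued)
#' @param params a [species_parameters()]
#' @param stochastic draw survivors binomially?
#' @return surviving weight
#' @export
post_spawning_survival <- function(weight, params, stochastic = FALSE) {
  stopifnot(all(weight >= 0))
  if (!stochastic) return(weight * params$sp_sp)
  n <- floor(weight)
  frac <- weight - n
  n <- n + stats::rbinom(base::length(weight), 1, frac)
  stats::rbinom(base::length(weight), n, params$sp_sp)
}

#' Maturity test
#'
#' A fish is mature once its length reaches the length at first maturity
#' (boundary inclusive).
#'
#' @param length fork length(s), cm
#' @param params a [species_parameters()]
#' @return logical
#' @export
is_mature <- function(length, params) {
  length >= params$l_mat
}
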