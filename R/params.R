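#' Thermal response triplet
#'
#' A dome-shaped thermal performance window defined by a lower bound, an
#' optimum and an upper bound (degrees Celsius). Performance is 1 at the
#' optimum and falls to 0 at (and beyond) both bounds; see [thermal_dome()].
#'
#' @param tmin lower temperature bound (degC)
#' @param topt optimal temperature (degC)
#' @param tmax upper temperature bound (degC)
#' @return an object of class `thermal_response`
#' @examples
#' thermal_response(3, 17, 26)
#' @export
thermal_response <- function(tmin, topt, tmax) {
  stopifnot(is.numeric(tmin), is.numeric(tmax), is.numeric(topt),
            length(tmin) == 1, length(topt) == 1, length(tmax) == 1,
            is.finite(tmin), is.finite(topt), is.finite(tmax))
  if (!(tmin < topt && topt < tmax))
    stop("thermal response requires tmin < topt < tmax, got (",
         tmin, ", ", topt, ", ", tmax, ")")
  structure(list(tmin = tmin, topt = topt, tmax = tmax),
            class = "thermal_response")
}

#' @export
print.thermal_response <- function(x, ...) {
  cat(sprintf("<thermal response: %g / %g / %g degC (min/opt/max)>\n",
              x$tmin, x$topt, x$tmax))
  invisible(x)
}

# Canonical season labels; the simulator's year is cut into calendar quarters
# (winter = JFM, spring = AMJ, summer = JAS, fall = OND).
SEASONS <- c("winter", "spring", "summer", "fall")

.param_names <- c(
  "rep_season", "dt_rec", "eta", "theta", "fecundity", "surv_opt_rep",
  "tmin_rep", "topt_rep", "tmax_rep", "lambda_rec", "sigma_rep", "sp_sp",
  "down_mig_age", "down_mig_season", "l_ini", "sigma_dl", "l_inf",
  "tmin_grow", "topt_grow", "tmax_grow", "k_opt_grow", "z_sea", "h_riv",
  "tmin_surv_riv", "topt_surv_riv", "tmax_surv_riv", "surv_opt_riv",
  "l_mat", "up_mig_season", "p_hom", "alpha_const", "alpha_dist",
  "alpha_tl", "alpha_wa", "dist_mean", "dist_sd", "tl_mean", "tl_sd",
  "wa_mean", "wa_sd", "w_death_basin")

#' Species life-history parameters
#'
#' Assembles the full parameter set of the mechanistic simulator. Defaults are
#' the nominal allis shad (*Alosa alosa*) parameterization; parameters whose
#' plausible range (rather than a point value) is known default to the centre
#' of that range (see [parameter_ranges()]).
#'
#' Units and meaning:
#' \describe{
#'   \item{rep_season, down_mig_season, up_mig_season}{season labels gating
#'     reproduction, the seaward juvenile run and the upstream spawning run.}
#'   \item{dt_rec}{assumed age (years) of the juveniles produced by a
#'     reproduction event ("recruits").}
#'   \item{eta, theta}{Allee-effect shape: the number of spawners at which
#'     95\% effectively reproduce is `eta * wa` (ind., with `wa` the basin
#'     area in km2) and the 50\% point is `eta * wa / theta`.}
#'   \item{fecundity}{eggs per individual.}
#'   \item{surv_opt_rep, tmin_rep, topt_rep, tmax_rep}{optimal egg-to-recruit
#'     survival and its thermal window.}
#'   \item{lambda_rec}{asymptotic recruitment per m2 of drainage area; the
#'     Beverton-Holt capacity of basin j is `lambda_rec * wa_j * 1e6`.}
#'   \item{sigma_rep, sigma_dl}{log-scale standard deviations of the
#'     recruitment and growth-increment log-normal noises.}
#'   \item{sp_sp}{post-spawning survival probability (iteroparity rate).}
#'   \item{l_ini, l_inf, k_opt_grow, tmin_grow, topt_grow, tmax_grow}{initial
#'     juvenile length (cm), asymptotic length (cm), per-season von
#'     Bertalanffy rate at the thermal optimum, and the growth thermal
#'     window.}
#'   \item{z_sea, h_riv}{annual mortality coefficients at sea and (on top of
#'     the thermal response) in river.}
#'   \item{surv_opt_riv, tmin_surv_riv, topt_surv_riv, tmax_surv_riv}{optimal
#'     annual river survival and its thermal window.}
#'   \item{l_mat}{length at first maturity (cm).}
#'   \item{p_hom}{probability of natal homing on the upstream run.}
#'   \item{alpha_const, alpha_dist, alpha_tl, alpha_wa, dist_mean, dist_sd,
#'     tl_mean, tl_sd, wa_mean, wa_sd}{coefficients and standardization
#'     constants of the logit accessibility/attractiveness weight used by
#'     straying fish (see [basin_weight()]).}
#'   \item{w_death_basin}{weight of the virtual death basin absorbing strays
#'     that fail to reach any river.}
#' }
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return an object of class `species_parameters` (a validated named list)
#' @examples
#' p <- species_parameters()
#' p$p_hom
#' species_parameters(tmin_rep = 9.8, k_opt_grow = 0.3)$tmin_rep
#' @export
species_parameters <- function(...) {
  p <- list(
    rep_season      = "spring",
    dt_rec          = 0.33,
    eta             = 2.4,
    theta           = 2.0,
    fecundity       = 135000,
    surv_opt_rep    = 7.5e-4,
    tmin_rep        = 10.5,
    topt_rep        = 20,
    tmax_rep        = 26,
    lambda_rec      = 4e-4,
    sigma_rep       = 0.2,
    sp_sp           = 0.1,
    down_mig_age    = 0.33,
    down_mig_season = "summer",
    l_ini           = 2,
    sigma_dl        = 0.2,
    l_inf           = 60,
    tmin_grow       = 3,
    topt_grow       = 17,
    tmax_grow       = 26,
    k_opt_grow      = 0.35,
    z_sea           = 0.4,
    h_riv           = 0,
    tmin_surv_riv   = 9.5,
    topt_surv_riv   = 20,
    tmax_surv_riv   = 30,
    surv_opt_riv    = 1,
    l_mat           = 40,
    up_mig_season   = "spring",
    p_hom           = 0.75,
    alpha_const     = -2.9,
    alpha_dist      = 19.7,
    alpha_tl        = 0,
    alpha_wa        = 0,
    dist_mean       = 300,
    dist_sd         = 978,
    tl_mean         = NA_real_,
    tl_sd           = NA_real_,
    wa_mean         = NA_real_,
    wa_sd           = NA_real_,
    w_death_basin   = 0.4)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown species parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_species_parameters(p)
}

validate_species_parameters <- function(p) {
  missing <- setdiff(.param_names, names(p))
  if (length(missing))
    stop("missing species parameter(s): ", paste(missing, collapse = ", "))
  num1 <- function(x, nm, allow_na = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || (!allow_na && !is.finite(x)))
      stop("parameter '", nm, "' must be a single finite number")
  }
  for (nm in setdiff(.param_names,
                     c("rep_season", "down_mig_season", "up_mig_season",
                       "tl_mean", "tl_sd", "wa_mean", "wa_sd")))
    num1(p[[nm]], nm)
  for (nm in c("tl_mean", "tl_sd", "wa_mean", "wa_sd"))
    num1(p[[nm]], nm, allow_na = TRUE)
  for (nm in c("rep_season", "down_mig_season", "up_mig_season"))
    if (!is.character(p[[nm]]) || length(p[[nm]]) != 1 ||
        !(p[[nm]] %in% SEASONS))
      stop("parameter '", nm, "' must be one of: ",
           paste(SEASONS, collapse = ", "))
  probs <- c("surv_opt_rep", "sp_sp", "surv_opt_riv", "p_hom")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must be a probability in [0, 1]")
  if (p$eta <= 0) stop("eta must be > 0")
  if (p$theta <= 1) stop("theta must be > 1")
  if (p$fecundity <= 0) stop("fecundity must be > 0")
  if (p$l_inf <= p$l_ini) stop("l_inf must exceed l_ini")
  if (p$sigma_rep < 0 || p$sigma_dl < 0)
    stop("log-normal standard deviations must be >= 0")
  if (p$w_death_basin < 0) stop("w_death_basin must be >= 0")
  if (p$z_sea < 0 || p$h_riv < 0)
    stop("mortality coefficients must be >= 0")
  # thermal windows must be well ordered
  thermal_response(p$tmin_rep, p$topt_rep, p$tmax_rep)
  thermal_response(p$tmin_grow, p$topt_grow, p$tmax_grow)
  thermal_response(p$tmin_surv_riv, p$topt_surv_riv, p$tmax_surv_riv)
  structure(p, class = "species_parameters")
}

#' @export
print.species_parameters <- function(x, ...) {
  cat("<species parameters:", length(.param_names), "values>\n")
  cat(sprintf("  reproduction: %s, eta = %g, theta = %g, fecundity = %g\n",
              x$rep_season, x$eta, x$theta, x$fecundity))
  cat(sprintf("  growth: l_inf = %g cm, k_opt_grow = %g/season\n",
              x$l_inf, x$k_opt_grow))
  cat(sprintf("  survival: z_sea = %g/yr, river window (%g, %g, %g) degC\n",
              x$z_sea, x$tmin_surv_riv, x$topt_surv_riv, x$tmax_surv_riv))
  cat(sprintf("  dispersal: p_hom = %g, death-basin weight = %g\n",
              x$p_hom, x$w_death_basin))
  invisible(x)
}

#' Thermal window accessors
#'
#' Extract the egg-to-recruit, growth, or river-survival thermal response
#' from a parameter set.
#'
#' @param params a [species_parameters()] object
#' @return a [thermal_response()] object
#' @export
thermal_rep <- function(params)
  thermal_response(params$tmin_rep, params$topt_rep, params$tmax_rep)

#' @rdname thermal_rep
#' @export
thermal_grow <- function(params)
  thermal_response(params$tmin_grow, params$topt_grow, params$tmax_grow)

#' @rdname thermal_rep
#' @export
thermal_surv_riv <- function(params)
  thermal_response(params$tmin_surv_riv, params$topt_surv_riv,
                   params$tmax_surv_riv)

#' Plausible ranges of the uncertain parameters
#'
#' Min-max intervals for the 11 parameters treated as uncertain in the
#' sensitivity analysis and calibration of the allis shad parameterization.
#' The default value of each such parameter in [species_parameters()] is the
#' centre of its interval.
#'
#' @return a named list of length-2 numeric vectors `c(min, max)`
#' @examples
#' length(parameter_ranges())  # 11
#' @export
parameter_ranges <- function() {
  list(
    theta         = c(1.8, 2.2),
    surv_opt_rep  = c(5e-4, 1e-3),
    tmin_rep      = c(9, 12),
    lambda_rec    = c(3e-4, 5e-4),
    topt_grow     = c(15, 19),
    k_opt_grow    = c(0.2, 0.5),
    z_sea         = c(0.2, 0.6),
    tmin_surv_riv = c(8, 11),
    l_mat         = c(36, 44),
    p_hom         = c(0.6, 0.9),
    w_death_basin = c(0.2, 0.6))
}

#' Read / write species parameters as YAML
#'
#' The on-disk format is a flat YAML mapping with exactly the names of
#' [species_parameters()]. Unknown keys are rejected and, when
#' `strict = TRUE` (the default), every parameter must be present so that a
#' configuration cannot silently fall back to package defaults.
#'
#' @param path file path
#' @param strict require all parameters to be present
#' @param params a `species_parameters` object
#' @return `read_species_parameters()` returns a `species_parameters`
#'   object; `write_species_parameters()` returns `path` invisibly.
#' @export
read_species_parameters <- function(path, strict = TRUE) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("parameter file must be a YAML mapping: ", path)
  unknown <- setdiff(names(raw), .param_names)
  if (length(unknown))
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  if (strict) {
    missing <- setdiff(.param_names, names(raw))
    if (length(missing))
      stop("parameter file is missing parameter(s): ",
           paste(missing, collapse = ", "))
  }
  # YAML has no NA literal; accept NULL/"NA"/".na" for the optional constants
  raw <- lapply(raw, function(x) {
    if (is.null(x) || (is.character(x) && x %in% c("NA", ".na"))) NA_real_
    else x
  })
  do.call(species_parameters, raw)
}

#' @rdname read_species_parameters
#' @export
write_species_parameters <- function(params, path) {
  stopifnot(inherits(params, "species_parameters"))
  out <- lapply(unclass(params), function(x)
    if (is.numeric(x) && is.na(x)) "NA" else x)
  yaml::write_yaml(out, path)
  invisible(path)
}
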