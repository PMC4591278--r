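#' Simulation configuration
#'
#' @param years simulated years (one year = four seasonal steps; the first
#'   step of a run is the summer seeding step, so a simulation year runs
#'   summer, fall, winter, spring and ends with the spring reproduction)
#' @param initial_juveniles_per_basin juveniles of length `l_ini` and age
#'   `dt_rec` placed in every basin at the first (summer) step
#' @param spinup_years number of years under the constant-reference climate
#'   regime; defaults to `years` (a fully stationary run, as used during
#'   calibration). Years beyond the spin-up follow the stored series.
#' @param series_start first calendar year of the stored climate series to
#'   use after spin-up (default: the first year of the series)
#' @param seed base RNG seed
#' @param replicate_id replicate index; the effective seed is derived
#'   deterministically from `(seed, replicate_id)`
#' @param max_age maximum tracked age in years; fish ageing beyond it die
#' @param dispersal `"stochastic"` (integer homing/stray split and
#'   multinomial destination draws, faithful to the individual-based
#'   process) or `"expected"` (deterministic allocation of super-individual
#'   weight by the destination probabilities)
#' @param stochastic_recruitment,stochastic_growth switch the log-normal
#'   noises off for deterministic runs (they are also off whenever the
#'   corresponding sigma is 0)
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(years,
                              initial_juveniles_per_basin = 500000,
                              spinup_years = years,
                              series_start = NULL,
                              seed = 1L,
                              replicate_id = 0L,
                              max_age = 20,
                              dispersal = c("stochastic", "expected"),
                              stochastic_recruitment = TRUE,
                              stochastic_growth = TRUE) {
  dispersal <- match.arg(dispersal)
  stopifnot(years >= 1, initial_juveniles_per_basin >= 0,
            spinup_years >= 0, spinup_years <= years, max_age >= 1)
  structure(list(years = as.integer(years),
                 seasons_per_year = 4L,
                 initial_juveniles_per_basin = initial_juveniles_per_basin,
                 spinup_years = as.integer(spinup_years),
                 series_start = series_start,
                 seed = as.integer(seed),
                 replicate_id = as.integer(replicate_id),
                 max_age = max_age,
                 dispersal = dispersal,
                 stochastic_recruitment = stochastic_recruitment,
                 stochastic_growth = stochastic_growth),
            class = "simulation_config")
}

derive_seed <- function(seed, replicate_id) {
  as.integer((as.double(seed) + 1000003 * as.double(replicate_id)) %%
               2147483647)
}

# Order of the seasonal cycle within a simulation year (seeding in summer).
.sim_seasons <- c("summer", "fall", "winter", "spring")

# Water temperature matrix [basin x tick] for the whole run: spin-up years
# use the constant reference regime, later years follow the stored series.
# Missing coverage aborts, naming the offending (basin, year, season).
resolve_temperatures <- function(network, climate, config) {
  ids <- network$basins$id
  if (!all(ids %in% climate$basins))
    stop("climate series does not cover basin(s): ",
         paste(setdiff(ids, climate$basins), collapse = ", "))
  nb <- length(ids)
  nticks <- config$years * 4L
  Tm <- matrix(NA_real_, nb, nticks)
  ref <- climate$reference[ids, , drop = FALSE]
  series_start <- if (is.null(config$series_start)) min(climate$years)
                  else as.integer(config$series_start)
  for (t in seq_len(nticks)) {
    season <- .sim_seasons[(t - 1L) %% 4L + 1L]
    y <- (t - 1L) %/% 4L + 1L
    if (y <= config$spinup_years) {
      Tm[, t] <- ref[, season]
    } else {
      cy <- series_start + (y - config$spinup_years - 1L)
      ycol <- as.character(cy)
      if (!ycol %in% dimnames(climate$temperatures)[[2]])
        stop(sprintf("no climate stored for (%s, %d, %s)", ids[1], cy, season))
      v <- climate$temperatures[ids, ycol, season]
      if (anyNA(v))
        stop(sprintf("no climate stored for (%s, %d, %s)",
                     ids[which(is.na(v))[1]], cy, season))
      Tm[, t] <- v
    }
  }
  if (anyNA(Tm)) stop("unresolved temperatures in reference regime")
  Tm
}

# Destination probability rows [cell x (nb + 1)] for straying fish. With a
# zero length coefficient the rows depend only on the natal basin and P is
# precomputed once; otherwise they are rebuilt from the cell lengths.
dispersal_prob_matrix <- function(network, params, fish_length = NA) {
  D <- network$distances
  wa <- network$basins$surface_area
  nb <- nrow(D)
  P <- matrix(0, nb, nb + 1L)
  for (j in seq_len(nb)) {
    w <- basin_weight(D[j, ], fish_length = fish_length, wa = wa,
                      params = params)
    P[j, ] <- destination_probabilities(w, params$w_death_basin)
  }
  P
}

#' Run the seasonal life-cycle simulation
#'
#' Executes the full anadromous life cycle over a basin network: every
#' seasonal step resolves temperatures, applies survival (sea or river by
#' location), grows fish at sea, checks maturation, runs the season-gated
#' migrations (upstream dispersal with homing/straying in the upstream
#' season, reproduction with post-spawning survival in the reproduction
#' season, seaward runs of juveniles and spent spawners in the downstream
#' season) and finally ages everyone by a quarter year. The population is
#' held as super-individual weight and mean-length arrays indexed by
#' age class and basin, split by location (sea/river) and spawning history
#' (first-time vs repeat), so a step is a fixed set of vectorized array
#' operations. Runs are exactly reproducible for a fixed
#' `(seed, replicate_id)`.
#'
#' @param network a [basin_network()]
#' @param climate a [climate_series()] covering the run (see
#'   [simulation_config()] for the spin-up/series schedule)
#' @param params a [species_parameters()]
#' @param config a [simulation_config()]
#' @return an object of class `simulation_result` with per-(year, basin)
#'   matrices `recruits`, `spawners`, `reproduction` (logical), and the
#'   weighted age records of first-time spawners; plus the tick count and
#'   the inputs needed by downstream summaries
#' @export
run_simulation <- function(network, climate, params, config) {
  stopifnot(inherits(network, "basin_network"),
            inherits(climate, "climate_series"),
            inherits(params, "species_parameters"),
            inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, config$replicate_id))

  ids <- network$basins$id
  nb <- length(ids)
  wa <- network$basins$surface_area
  nticks <- config$years * 4L
  Tm <- resolve_temperatures(network, climate, config)

  # age classes: class i holds fish of age dt_rec + (i - 1) * 0.25 years
  A <- as.integer(ceiling((config$max_age - params$dt_rec) / 0.25)) + 1L
  ages <- params$dt_rec + (seq_len(A) - 1L) * 0.25

  # per-tick demographic rates, precomputed over the whole temperature grid
  sea_surv <- sea_survival_probability(params)
  riv_surv <- river_survival_probability(Tm, params)          # nb x nticks
  grow_fac <- 1 - exp(-params$k_opt_grow *
                        thermal_dome(Tm, thermal_grow(params)))
  egg_surv <- params$surv_opt_rep * thermal_dome(Tm, thermal_rep(params))
  bh_alpha <- params$lambda_rec * wa * 1e6

  generic_weights <- params$alpha_tl == 0
  P <- if (generic_weights) dispersal_prob_matrix(network, params) else NULL

  zeros <- function() matrix(0, A, nb)
  Wsv <- zeros(); Lsv <- zeros()   # at sea, never spawned (keyed by natal)
  Wsr <- zeros(); Lsr <- zeros()   # at sea, repeat spawners
  Wrv <- zeros(); Lrv <- zeros()   # in river, never spawned (current basin)
  Wrr <- zeros(); Lrr <- zeros()   # in river, repeat spawners

  # initial seeding: juveniles in every basin at the first (summer) step
  init_class <- which.min(abs(ages - params$dt_rec))
  Wrv[init_class, ] <- config$initial_juveniles_per_basin
  Lrv[init_class, ] <- params$l_ini

  recruits <- matrix(0, config$years, nb, dimnames = list(NULL, ids))
  spawners <- matrix(0, config$years, nb, dimnames = list(NULL, ids))
  reproduction <- matrix(FALSE, config$years, nb, dimnames = list(NULL, ids))
  spage_sum <- matrix(0, config$years, nb, dimnames = list(NULL, ids))
  spage_w <- matrix(0, config$years, nb, dimnames = list(NULL, ids))

  sdl <- params$sigma_dl
  use_growth_noise <- config$stochastic_growth && sdl > 0
  use_rec_noise <- config$stochastic_recruitment && params$sigma_rep > 0
  stoch_disp <- config$dispersal == "stochastic"
  down_classes <- ages >= params$down_mig_age

  merge_in <- function(W, L, dW, dL_num) {
    # add weight dW with length numerator dL_num (= sum of weight x length)
    num <- W * L + dL_num
    W2 <- W + dW
    L2 <- num / W2
    L2[W2 <= 0] <- 0
    list(W = W2, L = L2)
  }

  for (t in seq_len(nticks)) {
    season <- .sim_seasons[(t - 1L) %% 4L + 1L]
    y <- (t - 1L) %/% 4L + 1L

    ## survival
    Wsv <- Wsv * sea_surv
    Wsr <- Wsr * sea_surv
    rs <- rep(riv_surv[, t], each = A)
    Wrv <- Wrv * rs
    Wrr <- Wrr * rs

    ## growth at sea (temperature of the adjacent basin's column)
    fac <- rep(grow_fac[, t], each = A)
    if (use_growth_noise) {
      dl <- (params$l_inf - Lsv) * fac *
        exp(stats::rnorm(A * nb, 0, sdl) - sdl^2 / 2)
      Lsv <- pmin(Lsv + dl, params$l_inf)
      if (any(Wsr > 0)) {
        dl <- (params$l_inf - Lsr) * fac *
          exp(stats::rnorm(A * nb, 0, sdl) - sdl^2 / 2)
        Lsr <- pmin(Lsr + dl, params$l_inf)
      }
    } else {
      Lsv <- pmin(Lsv + (params$l_inf - Lsv) * fac, params$l_inf)
      Lsr <- pmin(Lsr + (params$l_inf - Lsr) * fac, params$l_inf)
    }

    ## upstream migration: mature fish at sea run into rivers
    if (season == params$up_mig_season) {
      for (pool in c("v", "r")) {
        W <- if (pool == "v") Wsv else Wsr
        L <- if (pool == "v") Lsv else Lsr
        mat <- (L >= params$l_mat) & (W > 0)
        if (!any(mat)) next
        idx <- which(mat)
        w <- W[idx]
        len <- L[idx]
        natal <- (idx - 1L) %/% A + 1L
        W[idx] <- 0

        prows <- if (generic_weights) P[natal, , drop = FALSE]
                 else t(vapply(seq_along(idx), function(q) {
                   wts <- basin_weight(network$distances[natal[q], ],
                                       fish_length = len[q], wa = wa,
                                       params = params)
                   destination_probabilities(wts, params$w_death_basin)
                 }, numeric(nb + 1L)))

        if (stoch_disp) {
          n_stray <- stats::rbinom(length(w), floor(w), 1 - params$p_hom)
          hom <- w - n_stray
          alloc <- rmultinom_rows(n_stray, prows)
        } else {
          hom <- w * params$p_hom
          stray <- w - hom
          alloc <- stray * prows
        }
        cls <- (idx - 1L) %% A + 1L
        dW <- matrix(0, A, nb)
        dN <- matrix(0, A, nb)
        # homing fish return to the natal column
        hidx <- cbind(cls, natal)
        dW[hidx] <- dW[hidx] + hom
        dN[hidx] <- dN[hidx] + hom * len
        # strays settle where the multinomial/expected allocation sends them
        for (k in seq_len(nb)) {
          ak <- alloc[, k]
          nz <- ak > 0
          if (any(nz)) {
            tgt <- cbind(cls[nz], k)
            dW[tgt] <- dW[tgt] + ak[nz]
            dN[tgt] <- dN[tgt] + ak[nz] * len[nz]
          }
        }
        if (pool == "v") {
          m <- merge_in(Wrv, Lrv, dW, dN); Wrv <- m$W; Lrv <- m$L; Wsv <- W
        } else {
          m <- merge_in(Wrr, Lrr, dW, dN); Wrr <- m$W; Lrr <- m$L; Wsr <- W
        }
      }
    }

    ## reproduction
    if (season == params$rep_season) {
      mat_v <- Lrv >= params$l_mat
      mat_r <- Lrr >= params$l_mat
      Sv <- colSums(Wrv * mat_v)
      Sr <- colSums(Wrr * mat_r)
      S <- Sv + Sr
      surv_t <- egg_surv[, t]
      ok <- S > 0 & surv_t > 0
      Rdet <- numeric(nb)
      if (any(ok)) {
        s_eff <- effective_spawners(S[ok], wa[ok], params$eta, params$theta)
        beta <- bh_alpha[ok] / (params$fecundity * surv_t[ok])
        Rdet[ok] <- beverton_holt(s_eff, bh_alpha[ok], beta)
      }
      R <- if (use_rec_noise)
        Rdet * exp(stats::rnorm(nb, 0, params$sigma_rep) -
                     params$sigma_rep^2 / 2)
      else Rdet
      R[Rdet == 0] <- 0

      spawners[y, ] <- S
      recruits[y, ] <- R
      reproduction[y, ] <- Rdet > 0
      spage_sum[y, ] <- colSums(Wrv * mat_v * ages)
      spage_w[y, ] <- Sv

      # post-spawning survival; surviving first-timers become repeats
      surv_v <- Wrv * mat_v * params$sp_sp
      m <- merge_in(Wrr * ifelse(mat_r, params$sp_sp, 1), Lrr, surv_v,
                    surv_v * Lrv)
      Wrr <- m$W; Lrr <- m$L
      Wrv <- Wrv * !mat_v

      # recruits appear in the youngest class of their natal basin
      m <- merge_in(Wrv, Lrv,
                    dW = rbind(R, matrix(0, A - 1L, nb)),
                    dL_num = rbind(R * params$l_ini, matrix(0, A - 1L, nb)))
      Wrv <- m$W; Lrv <- m$L
    }

    ## downstream migration: river fish old enough head to sea
    if (season == params$down_mig_season) {
      dm <- down_classes & (rowSums(Wrv) + rowSums(Wrr) > 0)
      if (any(dm)) {
        mWv <- Wrv * down_classes
        mWr <- Wrr * down_classes
        m <- merge_in(Wsv, Lsv, mWv, mWv * Lrv); Wsv <- m$W; Lsv <- m$L
        m <- merge_in(Wsr, Lsr, mWr, mWr * Lrr); Wsr <- m$W; Lsr <- m$L
        Wrv <- Wrv * !down_classes
        Wrr <- Wrr * !down_classes
      }
    }

    ## ageing by a quarter year (the oldest class dies out)
    shift <- function(M) { M[2:A, ] <- M[seq_len(A - 1L), ]; M[1L, ] <- 0; M }
    Wsv <- shift(Wsv); Lsv <- shift(Lsv)
    Wsr <- shift(Wsr); Lsr <- shift(Lsr)
    Wrv <- shift(Wrv); Lrv <- shift(Lrv)
    Wrr <- shift(Wrr); Lrr <- shift(Lrr)
    Lsv[Wsv == 0] <- 0; Lsr[Wsr == 0] <- 0
    Lrv[Wrv == 0] <- 0; Lrr[Wrr == 0] <- 0
  }

  total_weight <- sum(Wsv) + sum(Wsr) + sum(Wrv) + sum(Wrr)
  structure(list(recruits = recruits, spawners = spawners,
                 reproduction = reproduction,
                 spawner_age_sum = spage_sum, spawner_age_weight = spage_w,
                 final_total_weight = total_weight,
                 ticks = nticks, years = config$years,
                 basin_ids = ids, latitudes = network$basins$lat,
                 config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation result: %d years (%d seasonal steps), %d basins>\n",
              x$years, x$ticks, length(x$basin_ids)))
  cat(sprintf("  final-year spawners: %.0f, recruits: %.0f\n",
              sum(x$spawners[x$years, ]), sum(x$recruits[x$years, ])))
  invisible(x)
}

terminal_window <- function(result, window_years) {
  stopifnot(window_years >= 1, window_years <= result$years)
  seq(result$years - window_years + 1L, result$years)
}

#' Per-basin persistence probability
#'
#' Fraction of years with successful reproduction over the terminal window
#' of a run: the probability of a basin to sustain a stable population.
#'
#' @param result a [run_simulation()] result
#' @param window_years terminal window length (years)
#' @return named numeric vector in \[0, 1\], one entry per basin
#' @export
persistence_probability <- function(result, window_years = 10) {
  win <- terminal_window(result, window_years)
  colMeans(result$reproduction[win, , drop = FALSE])
}

#' Populated basins under the recruitment rule
#'
#' Basins whose mean recruitment over the terminal window strictly exceeds
#' the threshold (nominally 50 juveniles over the last ten years); such
#' basins are considered populated and not on a crash trajectory.
#'
#' @param result a [run_simulation()] result
#' @param recruitment_threshold strict lower bound on mean recruitment
#' @param window_years terminal window length (years)
#' @return character vector of basin ids
#' @export
populated_basins <- function(result, recruitment_threshold = 50,
                             window_years = 10) {
  win <- terminal_window(result, window_years)
  mean_rec <- colMeans(result$recruits[win, , drop = FALSE])
  result$basin_ids[mean_rec > recruitment_threshold]
}

#' Mean age of first-time spawners
#'
#' Weight-averaged age of first-time spawners per basin over the terminal
#' window; `NA` for basins without any first-time spawner in the window.
#'
#' @param result a [run_simulation()] result
#' @param window_years terminal window length (years)
#' @return named numeric vector (years)
#' @export
mean_first_spawner_age <- function(result, window_years = 10) {
  win <- terminal_window(result, window_years)
  s <- colSums(result$spawner_age_sum[win, , drop = FALSE])
  w <- colSums(result$spawner_age_weight[win, , drop = FALSE])
  ifelse(w > 0, s / w, NA_real_)
}
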