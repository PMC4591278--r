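#' Homing versus straying decision
#'
#' On the upstream run each fish adopts natal homing with probability
#' `p_hom`, otherwise it strays and chooses a destination basin through the
#' weighted multinomial process ([destination_probabilities()],
#' [sample_destination()]).
#'
#' @param n number of independent decisions
#' @param p_hom homing probability in \[0, 1\]
#' @return logical vector, `TRUE` = homing
#' @export
stray_decision <- function(n = 1, p_hom) {
  stopifnot(p_hom >= 0, p_hom <= 1, n >= 0)
  stats::runif(n) < p_hom
}

#' Accessibility/attractiveness weight of a candidate basin
#'
#' Logit-linear weight combining dispersal distance (accessibility), fish
#' length (larger fish range farther) and basin drainage area
#' (attractiveness):
#' `plogis(alpha_const - alpha_dist * z_d + alpha_tl * z_l + alpha_wa * z_wa)`
#' with each `z` the covariate standardized by its mean/sd constants. The
#' distance term enters negatively so a positive `alpha_dist` makes nearby
#' basins near-certainly accessible and remote ones unreachable. Terms with
#' a zero coefficient vanish and their standardization constants (which may
#' be `NA`) are never touched; with a nonzero `alpha_tl` or `alpha_wa` the
#' corresponding constants must be supplied in the parameter set.
#'
#' @param distance dispersal distance(s) from the natal basin, km
#' @param fish_length fish length, cm (used only when `alpha_tl != 0`)
#' @param wa candidate basin surface area, km2 (used only when
#'   `alpha_wa != 0`)
#' @param params a [species_parameters()]
#' @return weight(s) in (0, 1)
#' @examples
#' basin_weight(300, params = species_parameters())  # plogis(-2.9)
#' basin_weight(0, params = species_parameters())    # ~0.959
#' @export
basin_weight <- function(distance, fish_length = NA, wa = NA, params) {
  stopifnot(all(distance >= 0))
  lp <- params$alpha_const -
    params$alpha_dist * (distance - params$dist_mean) / params$dist_sd
  if (params$alpha_tl != 0) {
    if (is.na(params$tl_mean) || is.na(params$tl_sd))
      stop("alpha_tl is nonzero but tl_mean/tl_sd are not supplied")
    lp <- lp + params$alpha_tl * (fish_length - params$tl_mean) / params$tl_sd
  }
  if (params$alpha_wa != 0) {
    if (is.na(params$wa_mean) || is.na(params$wa_sd))
      stop("alpha_wa is nonzero but wa_mean/wa_sd are not supplied")
    lp <- lp + params$alpha_wa * (wa - params$wa_mean) / params$wa_sd
  }
  stats::plogis(lp)
}

#' Destination probabilities over candidate basins and the death basin
#'
#' Standardizes the candidate-basin weights together with the death-basin
#' weight so they sum to one: each probability is
#' `weight / (sum(weights) + w_death)`. The death basin (last element,
#' named `"death"`) absorbs strays that fail to reach any river.
#'
#' @param weights non-negative weights, one per candidate basin (names kept)
#' @param w_death non-negative death-basin weight
#' @return probability vector of length `length(weights) + 1` summing to 1
#' @examples
#' destination_probabilities(c(2, 1, 1), w_death = 4)
#' @export
destination_probabilities <- function(weights, w_death) {
  stopifnot(is.numeric(weights), length(weights) >= 1,
            is.numeric(w_death), length(w_death) == 1)
  if (any(weights < 0) || w_death < 0)
    stop("weights must be non-negative")
  tot <- sum(weights) + w_death
  if (tot <= 0) stop("all destination weights are zero")
  p <- c(weights, w_death) / tot
  names(p) <- c(if (is.null(names(weights))) as.character(seq_along(weights))
                else names(weights), "death")
  p
}

#' Sample a dispersal destination
#'
#' One multinomial draw over the candidate basins and the death basin.
#'
#' @param probabilities vector from [destination_probabilities()]
#' @param n number of independent draws
#' @return character vector of destination names (possibly `"death"`)
#' @export
sample_destination <- function(probabilities, n = 1) {
  stopifnot(is.numeric(probabilities), all(probabilities >= 0),
            abs(sum(probabilities) - 1) < 1e-8)
  nm <- names(probabilities)
  if (is.null(nm)) nm <- as.character(seq_along(probabilities))
  nm[sample.int(length(probabilities), n, replace = TRUE,
                prob = probabilities)]
}

# Vectorized multinomial sampler: row i of `prob` is a probability vector,
# counts[i] trials are allocated across its columns via the sequential
# conditional-binomial construction. Returns an integer matrix of the same
# shape as `prob`. Used by the engine so dispersal of hundreds of cohorts
# costs ncol() vectorized rbinom calls rather than one rmultinom each.
rmultinom_rows <- function(counts, prob) {
  n <- length(counts)
  k <- ncol(prob)
  out <- matrix(0L, n, k)
  rem <- as.integer(counts)
  pleft <- rep(1, n)
  for (j in seq_len(k - 1L)) {
    pj <- prob[, j]
    pcond <- ifelse(pleft > 0, pmin(pmax(pj / pleft, 0), 1), 0)
    draw <- stats::rbinom(n, rem, pcond)
    out[, j] <- draw
    rem <- rem - draw
    pleft <- pleft - pj
  }
  out[, k] <- rem
  out
}
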