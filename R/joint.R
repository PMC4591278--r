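#' Probability classes for joint representation
#'
#' Converts probabilities to the five half-open classes used to display
#' suitability/persistence jointly: 0 is "null", (0, 0.25] "low",
#' (0.25, 0.53] "moderate", (0.53, 0.75] "high" and (0.75, 1] "very high".
#' The 0.53 cut matches the kappa-maximizing threshold of the reference
#' correlative model, so "moderate" vs "high" coincides with the binary
#' presence call.
#'
#' @param p probabilities in \[0, 1\] (vectorized)
#' @return factor with levels `null`, `low`, `moderate`, `high`,
#'   `very high`
#' @examples
#' probability_class(c(0, 0.25, 0.53, 0.75, 1))
#' @export
probability_class <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  lev <- c("null", "low", "moderate", "high", "very high")
  out <- cut(p, breaks = c(0, 0.25, 0.53, 0.75, 1), labels = lev[-1],
             include.lowest = FALSE, right = TRUE)
  out <- as.character(out)
  out[p == 0] <- "null"
  factor(out, levels = lev)
}

#' Geographic extent common to both model families
#'
#' Intersection of the basin sets covered by the correlative and mechanistic
#' models, on which any joint comparison must be made. The result preserves
#' a south-to-north latitude order when a network is supplied.
#'
#' @param correlative_basins,mechanistic_basins character vectors of basin
#'   ids
#' @param network optional [basin_network()] used to order the result by
#'   outlet latitude
#' @return character vector of shared basin ids
#' @export
common_extent <- function(correlative_basins, mechanistic_basins,
                          network = NULL) {
  shared <- intersect(as.character(correlative_basins),
                      as.character(mechanistic_basins))
  if (length(shared) == 0)
    stop("the two basin sets have no common geographic extent")
  if (!is.null(network)) {
    lat <- network$basins$lat[match(shared, network$basins$id)]
    shared <- shared[order(lat)]
  }
  shared
}

#' Joint comparison table of the two model families
#'
#' Per-basin, latitude-ordered table with the correlative suitability
#' probability, the mechanistic persistence probability, their probability
#' classes and a class-agreement flag, plus a heat-map-ready long format and
#' the across-basin probability means.
#'
#' @param p_suit named suitability probabilities (correlative model)
#' @param p_sust named persistence probabilities (mechanistic model)
#' @param network a [basin_network()] covering the shared ids
#' @param classes add probability-class columns?
#' @return an object of class `sdm_comparison`: list with `table` (wide,
#'   latitude-ordered), `long` (basin x model rows), `mean_p_suit`,
#'   `mean_p_sust`
#' @export
comparison_table <- function(p_suit, p_sust, network, classes = TRUE) {
  if (length(p_suit) == 0 || length(p_sust) == 0)
    stop("probability vectors must be non-empty")
  if (is.null(names(p_suit)) || is.null(names(p_sust)))
    stop("probability vectors must be named by basin id")
  ids <- common_extent(names(p_suit), names(p_sust), network)
  if (!setequal(names(p_suit), ids) || !setequal(names(p_sust), ids))
    stop("probability vectors do not cover the same basins; restrict to ",
         "the common extent first")
  lat <- network$basins$lat[match(ids, network$basins$id)]
  tab <- data.frame(id = ids, lat = lat,
                    p_suit = unname(p_suit[ids]),
                    p_sust = unname(p_sust[ids]),
                    stringsAsFactors = FALSE)
  if (classes) {
    tab$suit_class <- probability_class(tab$p_suit)
    tab$sust_class <- probability_class(tab$p_sust)
    tab$agreement <- tab$suit_class == tab$sust_class
  }
  long <- data.frame(
    id = rep(ids, 2), lat = rep(lat, 2),
    model = rep(c("correlative", "mechanistic"), each = length(ids)),
    probability = c(tab$p_suit, tab$p_sust), stringsAsFactors = FALSE)
  if (classes) long$class <- probability_class(long$probability)
  structure(list(table = tab, long = long,
                 mean_p_suit = mean(tab$p_suit),
                 mean_p_sust = mean(tab$p_sust)),
            class = "sdm_comparison")
}

#' @export
print.sdm_comparison <- function(x, ...) {
  cat(sprintf("<joint comparison: %d basins; mean p_suit %.3f, mean p_sust %.3f>\n",
              nrow(x$table), x$mean_p_suit, x$mean_p_sust))
  if (!is.null(x$table$agreement))
    cat(sprintf("  probability-class agreement: %d / %d basins\n",
                sum(x$table$agreement), nrow(x$table)))
  invisible(x)
}

#' Latitudinal range limits
#'
#' Southern and northern outlet latitudes among the basins that qualify:
#' probability at or above `class_threshold`, or a `TRUE` populated flag.
#' Undefined (`NA`) limits when no basin qualifies.
#'
#' @param x per-basin probabilities, or logical populated flags
#' @param latitudes matching outlet latitudes
#' @param class_threshold qualification threshold for probabilities
#' @return named vector `c(southern =, northern =)` (decimal degrees)
#' @export
range_limits <- function(x, latitudes, class_threshold = 0.53) {
  stopifnot(length(x) == length(latitudes))
  qual <- if (is.logical(x)) x else x >= class_threshold
  if (!any(qual)) return(c(southern = NA_real_, northern = NA_real_))
  c(southern = min(latitudes[qual]), northern = max(latitudes[qual]))
}

#' Joint interpretation report
#'
#' Confronts the two model families on the two patterns that drive
#' interpretation: (1) the overall trend in probabilities between a past
#' and a future period, and (2) the predicted range limits. Trends are
#' called congruent when both models move in the same direction within a
#' tolerance on the mean-probability change; range limits are congruent
#' when the northern and southern limits differ by no more than a latitude
#' tolerance. The verdicts come with the quantities they were computed
#' from; the tolerances are user choices, not fitted quantities.
#'
#' @param past,future `sdm_comparison` objects for the two periods
#' @param trend_tolerance absolute change in mean probability treated as
#'   "stable"
#' @param limit_tolerance_deg latitude difference (degrees) treated as
#'   congruent
#' @param class_threshold threshold defining range membership
#' @return an object of class `joint_report`
#' @export
joint_report <- function(past, future, trend_tolerance = 0.1,
                         limit_tolerance_deg = 1,
                         class_threshold = 0.53) {
  stopifnot(inherits(past, "sdm_comparison"), inherits(future, "sdm_comparison"))
  trend_of <- function(delta)
    if (abs(delta) <= trend_tolerance) "stable"
    else if (delta > 0) "increasing" else "decreasing"
  d_suit <- future$mean_p_suit - past$mean_p_suit
  d_sust <- future$mean_p_sust - past$mean_p_sust
  trends <- c(correlative = trend_of(d_suit), mechanistic = trend_of(d_sust))
  lim <- lapply(list(past = past, future = future), function(cmp) {
    list(correlative = range_limits(cmp$table$p_suit, cmp$table$lat,
                                    class_threshold),
         mechanistic = range_limits(cmp$table$p_sust, cmp$table$lat,
                                    class_threshold))
  })
  limit_delta <- vapply(lim, function(l) {
    if (anyNA(l$correlative) || anyNA(l$mechanistic)) NA_real_
    else max(abs(l$correlative - l$mechanistic))
  }, numeric(1))
  structure(list(
    trends = trends,
    trend_delta = c(correlative = d_suit, mechanistic = d_sust),
    trend_congruent = trends[1] == trends[2],
    range_limits = lim,
    limit_delta = limit_delta,
    limits_congruent = !is.na(limit_delta) & limit_delta <= limit_tolerance_deg,
    tolerances = c(trend = trend_tolerance, limit_deg = limit_tolerance_deg)),
    class = "joint_report")
}

#' @export
print.joint_report <- function(x, ...) {
  cat("<joint interpretation report>\n")
  cat(sprintf("  trends: correlative %s (%+.3f), mechanistic %s (%+.3f) -> %s\n",
              x$trends["correlative"], x$trend_delta["correlative"],
              x$trends["mechanistic"], x$trend_delta["mechanistic"],
              if (x$trend_congruent) "congruent forecasts"
              else "divergent forecasts"))
  for (period in names(x$limits_congruent)) {
    cat(sprintf("  %s range limits: %s (max |delta| = %.2f deg)\n", period,
                if (isTRUE(x$limits_congruent[[period]])) "congruent"
                else "not congruent", x$limit_delta[[period]]))
  }
  invisible(x)
}
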