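#' Generate a synthetic basin network
#'
#' A latitudinal chain of basins along a meridian-like coast: outlets evenly
#' spaced between the latitude bounds at a fixed longitude, with log-normal
#' drainage areas. Distances are great-circle between outlets. The default
#' emulates the structure of the north-east Atlantic study systems (a chain
#' from ~37 to ~60 degrees north with strongly heterogeneous basin sizes)
#' at a size where the full tool chain runs in seconds.
#'
#' @param n_basins number of basins
#' @param lat_range `c(south, north)` latitude bounds, decimal degrees
#' @param lon outlet longitude shared by the chain
#' @param area_meanlog,area_sdlog log-normal parameters of the surface area
#'   distribution (km2)
#' @param seed RNG seed
#' @return a [basin_network()]
#' @examples
#' net <- make_network(n_basins = 5, seed = 1)
#' range(net$basins$lat)
#' @export
make_network <- function(n_basins = 20, lat_range = c(37, 59.8), lon = -2,
                         area_meanlog = log(5000), area_sdlog = 1,
                         seed = 1) {
  stopifnot(n_basins >= 1, length(lat_range) == 2)
  set.seed(derive_seed(seed, 0L))
  lat <- if (n_basins == 1) mean(lat_range)
         else seq(lat_range[1], lat_range[2], length.out = n_basins)
  areas <- stats::rlnorm(n_basins, area_meanlog, area_sdlog)
  basins <- data.frame(
    id = sprintf("b%02d", seq_len(n_basins)),
    lon = lon, lat = lat, surface_area = areas,
    stringsAsFactors = FALSE)
  basin_network(basins)
}

# closed-form seasonal mean used by make_climate (exported logic kept in one
# place so tests can compare generated series against it)
season_offsets <- function(seasonal_amplitude) {
  c(winter = -1, spring = 0, summer = 1, fall = 0) * seasonal_amplitude
}

#' Generate a synthetic seasonal climate
#'
#' Seasonal water temperatures declining linearly with latitude, a fixed
#' seasonal cycle (summer warmer and winter colder than spring/fall by the
#' amplitude), an optional linear warming trend and small Gaussian noise:
#' `T(basin, year, season) = base - lapse * (lat - ref_lat) +
#' offset(season) + warming * (year - start_year) / 100 + noise`.
#' The first `reference_length` years double as the reference decade for
#' constant-climate phases.
#'
#' @param network a [basin_network()]
#' @param years number of years
#' @param start_year first calendar year
#' @param base_temp spring/fall water temperature at `ref_lat`, degC
#' @param ref_lat reference latitude of `base_temp`
#' @param lapse cooling per degree of latitude northward, degC/degree
#' @param seasonal_amplitude summer-minus-spring offset, degC
#' @param warming_per_century linear trend, degC per 100 years
#' @param noise_sd interannual Gaussian noise, degC
#' @param reference_length years defining the reference regime
#' @param seed RNG seed
#' @return a [climate_series()] (water medium)
#' @export
make_climate <- function(network, years = 60, start_year = 1901,
                         base_temp = 16, ref_lat = 37, lapse = 0.45,
                         seasonal_amplitude = 6, warming_per_century = 0,
                         noise_sd = 0.3, reference_length = 10, seed = 1) {
  stopifnot(inherits(network, "basin_network"), years >= 1)
  set.seed(derive_seed(seed, 1L))
  b <- network$basins
  yrs <- start_year + seq_len(years) - 1L
  offs <- season_offsets(seasonal_amplitude)
  grid <- expand.grid(basin_id = b$id, year = yrs, season = SEASONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lat <- b$lat[match(grid$basin_id, b$id)]
  grid$temperature <- base_temp - lapse * (lat - ref_lat) +
    offs[grid$season] +
    warming_per_century * (grid$year - start_year) / 100 +
    (if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0)
  climate_series(grid, medium = "water",
                 reference_years = yrs[seq_len(min(reference_length, years))])
}

#' Generate a virtual-species historical distribution
#'
#' Presence flags from a thermal-suitability rule on the reference-regime
#' seasonal temperature: present where the dome response of the rule's
#' thermal window meets the threshold. Because the synthetic climate is
#' monotone in latitude, the resulting distribution is a contiguous
#' latitudinal band — the structure both model families assume. Optional
#' seeded contamination flips presences/absences at the stated rates, so
#' imperfect (false presence/absence) data can be emulated.
#'
#' @param network a [basin_network()]
#' @param climate a [climate_series()] covering the network
#' @param rule a [thermal_response()] defining suitability
#' @param threshold minimal dome response for presence, in \[0, 1\]
#' @param season season of the reference temperature used by the rule
#' @param false_presence,false_absence contamination rates in \[0, 1\]
#' @param seed RNG seed (used only when contamination is nonzero)
#' @return named logical vector of presence flags (basin ids as names)
#' @export
make_virtual_distribution <- function(network, climate,
                                      rule = thermal_response(10.5, 20, 26),
                                      threshold = 0.25, season = "spring",
                                      false_presence = 0, false_absence = 0,
                                      seed = 1) {
  stopifnot(inherits(network, "basin_network"),
            inherits(climate, "climate_series"),
            threshold >= 0, threshold <= 1)
  season <- match.arg(season, SEASONS)
  ids <- network$basins$id
  tref <- climate$reference[ids, season]
  pres <- thermal_dome(tref, rule) >= threshold
  if (false_presence > 0 || false_absence > 0) {
    set.seed(derive_seed(seed, 2L))
    flip_in <- !pres & stats::runif(length(pres)) < false_presence
    flip_out <- pres & stats::runif(length(pres)) < false_absence
    pres <- (pres | flip_in) & !flip_out
  }
  stats::setNames(as.logical(pres), ids)
}

#' Default synthetic study fixture
#'
#' Bundles a 20-basin network, a 60-year stationary climate and a
#' virtual-species distribution under the nominal species parameters — the
#' self-contained test bed used throughout the package examples and tests.
#'
#' @param n_basins,years,seed as in the individual generators
#' @param warming_per_century passed to [make_climate()]
#' @return list with `network`, `climate`, `observed`, `params`
#' @export
make_fixture <- function(n_basins = 20, years = 60, seed = 1,
                         warming_per_century = 0) {
  network <- make_network(n_basins = n_basins, seed = seed)
  climate <- make_climate(network, years = years,
                          warming_per_century = warming_per_century,
                          seed = seed)
  params <- species_parameters()
  observed <- make_virtual_distribution(network, climate,
                                        rule = thermal_rep(params),
                                        seed = seed)
  list(network = network, climate = climate, observed = observed,
       params = params)
}
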