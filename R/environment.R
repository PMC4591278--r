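#' Build a basin network
#'
#' A basin network is the physical environment of the simulator: an ordered
#' collection of river basins (outlet coordinates in decimal degrees, drainage
#' surface area in km2) plus a symmetric matrix of inter-basin distances (km).
#' When no distance matrix is supplied, great-circle distances between basin
#' outlets are used; a user matrix (e.g. along-coast route distances) passes
#' through after validation.
#'
#' @param basins data.frame with columns `id`, `lon`, `lat`, `surface_area`
#'   and optionally `main_stem`
#' @param distances optional square symmetric matrix (km) with zero diagonal,
#'   rows/columns ordered or named as `basins$id`
#' @return an object of class `basin_network`
#' @examples
#' b <- data.frame(id = c("a", "b"), lon = 0, lat = c(0, 1),
#'                 surface_area = c(1000, 2000))
#' net <- basin_network(b)
#' net$distances["a", "b"]  # ~111.2 km
#' @export
basin_network <- function(basins, distances = NULL) {
  stopifnot(is.data.frame(basins))
  req <- c("id", "lon", "lat", "surface_area")
  missing <- setdiff(req, names(basins))
  if (length(missing))
    stop("basin table is missing column(s): ", paste(missing, collapse = ", "))
  basins$id <- as.character(basins$id)
  if (anyDuplicated(basins$id)) stop("basin ids must be unique")
  if (any(!is.finite(basins$lat)) || any(abs(basins$lat) > 90))
    stop("basin latitudes must be finite and within [-90, 90]")
  if (any(!is.finite(basins$lon)))
    stop("basin longitudes must be finite")
  if (any(!is.finite(basins$surface_area)) || any(basins$surface_area <= 0))
    stop("basin surface areas must be positive")
  if (is.null(distances)) {
    distances <- pairwise_distances(basins)
  } else {
    distances <- as.matrix(distances)
    n <- nrow(basins)
    if (!is.numeric(distances) || nrow(distances) != n || ncol(distances) != n)
      stop("distance matrix must be numeric ", n, " x ", n)
    if (!is.null(rownames(distances))) {
      if (!setequal(rownames(distances), basins$id))
        stop("distance matrix row names do not match basin ids")
      distances <- distances[basins$id, basins$id]
    }
    if (any(!is.finite(distances)) || any(distances < 0))
      stop("distance matrix entries must be finite and non-negative")
    if (any(abs(distances - t(distances)) > 1e-8))
      stop("distance matrix must be symmetric")
    if (any(abs(diag(distances)) > 1e-8))
      stop("distance matrix must have a zero diagonal")
    dimnames(distances) <- list(basins$id, basins$id)
  }
  structure(list(basins = basins, distances = distances),
            class = "basin_network")
}

#' @export
print.basin_network <- function(x, ...) {
  cat(sprintf("<basin network: %d basins, latitudes %.2f to %.2f>\n",
              nrow(x$basins), min(x$basins$lat), max(x$basins$lat)))
  invisible(x)
}

#' Number of basins in a network
#' @param network a [basin_network()]
#' @export
n_basins <- function(network) nrow(network$basins)

#' Great-circle distances between basin outlets
#'
#' Haversine distances (Earth radius 6371 km) between every pair of basin
#' outlets. The result is symmetric with a zero diagonal.
#'
#' @param basins data.frame with `lon`, `lat` (decimal degrees, WGS84-like)
#'   and optionally `id` used for dimnames
#' @return matrix of distances in km
#' @export
pairwise_distances <- function(basins) {
  stopifnot(is.data.frame(basins), nrow(basins) >= 1,
            all(c("lon", "lat") %in% names(basins)))
  pts <- as.matrix(basins[, c("lon", "lat")])
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                       r = 6371) # km
  }
  d <- (d + t(d)) / 2  # enforce exact symmetry against float asymmetries
  diag(d) <- 0
  if (!is.null(basins$id))
    dimnames(d) <- list(as.character(basins$id), as.character(basins$id))
  d
}

#' Convert air to water temperature
#'
#' Water temperatures are taken to track air temperatures with a constant
#' 2 degC offset; all demographic processes consume water temperatures, so
#' air-medium climate inputs are converted on load.
#'
#' @param t_air air temperature(s), degC
#' @return water temperature(s), degC (`t_air - 2`)
#' @examples
#' air_to_water(18)  # 16
#' @export
air_to_water <- function(t_air) {
  stopifnot(is.numeric(t_air))
  if (any(!is.finite(t_air))) stop("air temperatures must be finite")
  t_air - 2
}

#' Seasonal climate series over a basin network
#'
#' Stores one mean temperature per (basin, year, season). Seasons are fixed
#' calendar quarters (winter = JFM, spring = AMJ, summer = JAS, fall = OND).
#' Air-medium input is converted to water with [air_to_water()]. A reference
#' seasonal regime (the per-basin, per-season mean over `reference_years`,
#' by default the first ten years present) supports constant-climate phases
#' such as simulation spin-up.
#'
#' @param data long data.frame with columns `basin_id`, `year`, `season`,
#'   `temperature`
#' @param medium `"water"` or `"air"`
#' @param reference_years integer vector of years defining the reference
#'   regime; default the first 10 (or all, if fewer) years in `data`
#' @return an object of class `climate_series`
#' @export
climate_series <- function(data, medium = c("water", "air"),
                           reference_years = NULL) {
  medium <- match.arg(medium)
  stopifnot(is.data.frame(data))
  req <- c("basin_id", "year", "season", "temperature")
  missing <- setdiff(req, names(data))
  if (length(missing))
    stop("climate table is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(data$season %in% SEASONS))
    stop("season labels must be among: ", paste(SEASONS, collapse = ", "))
  if (any(!is.finite(data$temperature))) stop("temperatures must be finite")
  temp <- if (medium == "air") air_to_water(data$temperature) else data$temperature
  basins <- unique(as.character(data$basin_id))
  years <- sort(unique(as.integer(data$year)))
  arr <- array(NA_real_, dim = c(length(basins), length(years), 4L),
               dimnames = list(basins, as.character(years), SEASONS))
  idx <- cbind(match(as.character(data$basin_id), basins),
               match(as.integer(data$year), years),
               match(as.character(data$season), SEASONS))
  if (anyDuplicated(idx))
    stop("duplicate (basin, year, season) rows in climate table")
  arr[idx] <- temp
  if (is.null(reference_years))
    reference_years <- years[seq_len(min(10L, length(years)))]
  if (!all(reference_years %in% years))
    stop("reference years not all present in the series")
  ref <- apply(arr[, as.character(reference_years), , drop = FALSE],
               c(1, 3), mean)
  structure(list(temperatures = arr, reference = ref,
                 basins = basins, years = years,
                 reference_years = as.integer(reference_years)),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf(
    "<climate series: %d basins, years %d-%d, reference %d-%d (water degC)>\n",
    length(x$basins), min(x$years), max(x$years),
    min(x$reference_years), max(x$reference_years)))
  invisible(x)
}

#' Resolve a seasonal temperature
#'
#' Looks a water temperature up in a [climate_series()] under one of three
#' regimes: `"constant-reference"` returns the reference-decade seasonal mean
#' regardless of year (used during spin-up), while `"observed-series"` and
#' `"scenario-series"` return the stored value for `(basin, year, season)`.
#' A missing value under a series regime is an error, never a silent
#' fallback.
#'
#' @param climate a [climate_series()]
#' @param basin basin id (character)
#' @param year integer year
#' @param season one of `"winter"`, `"spring"`, `"summer"`, `"fall"`
#' @param regime lookup regime
#' @return water temperature, degC
#' @export
temperature_at <- function(climate, basin, year, season,
                           regime = c("constant-reference", "observed-series",
                                      "scenario-series")) {
  regime <- match.arg(regime)
  stopifnot(inherits(climate, "climate_series"))
  basin <- as.character(basin)
  season <- match.arg(season, SEASONS)
  if (!basin %in% climate$basins)
    stop("unknown basin in climate series: ", basin)
  if (regime == "constant-reference")
    return(unname(climate$reference[basin, season]))
  yr <- as.character(as.integer(year))
  val <- if (yr %in% dimnames(climate$temperatures)[[2]])
    climate$temperatures[basin, yr, season] else NA_real_
  if (is.na(val))
    stop(sprintf("no temperature stored for (%s, %d, %s)",
                 basin, as.integer(year), season))
  unname(val)
}

#' Read a basin network from CSV
#'
#' Expects a header `id,lon,lat,surface_area_km2[,main_stem_km]`. An optional
#' distance matrix CSV must be square with id-labelled rows and columns.
#'
#' @param basins_csv path to the basin table
#' @param distances_csv optional path to a distance matrix
#' @return a [basin_network()]
#' @export
read_basin_network <- function(basins_csv, distances_csv = NULL) {
  tab <- utils::read.csv(basins_csv, stringsAsFactors = FALSE)
  req <- c("id", "lon", "lat", "surface_area_km2")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("basin CSV is missing column(s): ", paste(missing, collapse = ", "))
  basins <- data.frame(id = as.character(tab$id), lon = tab$lon,
                       lat = tab$lat, surface_area = tab$surface_area_km2,
                       stringsAsFactors = FALSE)
  if ("main_stem_km" %in% names(tab)) basins$main_stem <- tab$main_stem_km
  distances <- NULL
  if (!is.null(distances_csv)) {
    m <- utils::read.csv(distances_csv, row.names = 1, check.names = FALSE)
    distances <- as.matrix(m)
  }
  basin_network(basins, distances)
}

#' Read a seasonal climate series from CSV
#'
#' Long format with header `basin_id,year,season,temperature_C,medium`;
#' `medium` must be uniformly `"air"` or `"water"`.
#'
#' @param path CSV path
#' @param reference_years passed to [climate_series()]
#' @return a [climate_series()]
#' @export
read_climate_series <- function(path, reference_years = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("basin_id", "year", "season", "temperature_C", "medium")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("climate CSV is missing column(s): ", paste(missing, collapse = ", "))
  medium <- unique(tab$medium)
  if (length(medium) != 1 || !medium %in% c("air", "water"))
    stop("climate CSV must have a single medium, 'air' or 'water'")
  climate_series(
    data.frame(basin_id = tab$basin_id, year = tab$year, season = tab$season,
               temperature = tab$temperature_C, stringsAsFactors = FALSE),
    medium = medium, reference_years = reference_years)
}

#' Write helpers for the standard CSV formats
#'
#' @param network a [basin_network()]
#' @param climate a [climate_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_basin_network <- function(network, path) {
  b <- network$basins
  out <- data.frame(id = b$id, lon = b$lon, lat = b$lat,
                    surface_area_km2 = b$surface_area)
  if (!is.null(b$main_stem)) out$main_stem_km <- b$main_stem
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basin_network
#' @export
write_distance_matrix <- function(network, path) {
  utils::write.csv(as.data.frame(network$distances), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_basin_network
#' @export
write_climate_series <- function(climate, path) {
  arr <- climate$temperatures
  grid <- expand.grid(basin_id = climate$basins,
                      year = climate$years, season = SEASONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$temperature_C <- arr[cbind(match(grid$basin_id, climate$basins),
                                  match(grid$year, climate$years),
                                  match(grid$season, SEASONS))]
  grid$medium <- "water"
  grid <- grid[!is.na(grid$temperature_C), ]
  grid <- grid[order(grid$basin_id, grid$year, match(grid$season, SEASONS)), ]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
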