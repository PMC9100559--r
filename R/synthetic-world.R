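# IUCN Red List categories in increasing threat severity, and the binary
# grouping used throughout ("possibly threatened" = VU + EN + CR).
RL_CLASSES <- c("LC", "NT", "VU", "EN", "CR")
THREATENED_CLASSES <- c("VU", "EN", "CR")

#' Configuration for a toy world
#'
#' Defines the spatial scaffolding the synthetic occurrence generator places
#' species into: a lon/lat extent partitioned into latitudinal biome bands and
#' longitudinal country strips, a land mask (sea along the extent margin), a
#' smooth human-footprint field with a handful of high-pressure centers, a
#' linear latitude-temperature climate field, and a gazetteer of locations
#' whose neighbourhoods should not contain valid records (capitals, country
#' centroids, institutions).
#'
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)`, degrees.
#' @param n_biomes Number of biome bands (the global WWF scheme has 14).
#' @param n_countries Number of country strips.
#' @param raster_resolution_deg Raster cell size; must tile the extent exactly.
#' @param footprint_gradient List with `n_centers`, `amplitude`, `sigma_deg`,
#'   `baseline` describing the footprint field (sum of Gaussian bumps).
#' @param climate_lapse Temperature decrease per degree of absolute latitude.
#' @param sea_margin_frac Fraction of each extent side that is sea.
#' @param n_gazetteer Number of gazetteer entries per type.
#' @param seed Integer RNG seed.
#' @return A list of class `world_config`.
#' @export
world_config <- function(extent = c(-40, 40, -40, 40),
                         n_biomes = 14,
                         n_countries = 10,
                         raster_resolution_deg = 1,
                         footprint_gradient = list(
                           n_centers = 5, amplitude = 40,
                           sigma_deg = 8, baseline = 0.2
                         ),
                         climate_lapse = 0.6,
                         sea_margin_frac = 0.1,
                         n_gazetteer = 5,
                         seed = 1L) {
  extent <- as.numeric(extent)
  if (length(extent) != 4) stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  if (extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stop("invalid world config: degenerate extent (zero or negative width/height)")
  }
  if (extent[1] < -180 || extent[2] > 180 || extent[3] < -90 || extent[4] > 90) {
    stop("extent must lie within [-180, 180] x [-90, 90]")
  }
  if (n_biomes < 1) stop("n_biomes must be >= 1")
  if (n_countries < 1) stop("n_countries must be >= 1")
  w <- (extent[2] - extent[1]) / raster_resolution_deg
  h <- (extent[4] - extent[3]) / raster_resolution_deg
  if (abs(w - round(w)) > 1e-9 || abs(h - round(h)) > 1e-9) {
    stop("raster_resolution_deg must tile the extent exactly")
  }
  structure(
    list(
      extent = extent, n_biomes = n_biomes, n_countries = n_countries,
      raster_resolution_deg = raster_resolution_deg,
      footprint_gradient = footprint_gradient,
      climate_lapse = climate_lapse,
      sea_margin_frac = sea_margin_frac,
      n_gazetteer = n_gazetteer,
      seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

# Horizontal (biomes) or vertical (countries) band polygons partitioning
# the extent into n equal strips.
band_polygons <- function(extent, n, horizontal, prefix) {
  lo <- if (horizontal) extent[3] else extent[1]
  hi <- if (horizontal) extent[4] else extent[2]
  breaks <- seq(lo, hi, length.out = n + 1)
  rings <- lapply(seq_len(n), function(i) {
    a <- breaks[i]
    b <- breaks[i + 1]
    if (horizontal) {
      data.frame(
        lon = c(extent[1], extent[2], extent[2], extent[1]),
        lat = c(a, a, b, b)
      )
    } else {
      data.frame(
        lon = c(a, b, b, a),
        lat = c(extent[3], extent[3], extent[4], extent[4])
      )
    }
  })
  polygon_layer(
    ids = seq_len(n),
    names = paste0(prefix, "_", seq_len(n)),
    rings = rings
  )
}

#' Generate toy reference layers
#'
#' Deterministic given `config$seed`: the same configuration always yields
#' byte-identical layers.
#'
#' @param config A [world_config()].
#' @return A [reference_layers()] object.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  ext <- config$extent
  res <- config$raster_resolution_deg
  ncols <- round((ext[2] - ext[1]) / res)
  nrows <- round((ext[4] - ext[3]) / res)

  # cell-center coordinates, row 1 = northernmost
  cx <- ext[1] + (seq_len(ncols) - 0.5) * res
  cy <- ext[4] - (seq_len(nrows) - 0.5) * res
  lon_m <- matrix(cx, nrows, ncols, byrow = TRUE)
  lat_m <- matrix(cy, nrows, ncols)

  # land = inner rectangle, sea = margin ring
  mx <- config$sea_margin_frac * (ext[2] - ext[1])
  my <- config$sea_margin_frac * (ext[4] - ext[3])
  land_vals <- (lon_m >= ext[1] + mx) & (lon_m <= ext[2] - mx) &
    (lat_m >= ext[3] + my) & (lat_m <= ext[4] - my)
  land <- ascii_grid(land_vals * 1, ext[1], ext[3], res)

  fg <- config$footprint_gradient
  centers <- cbind(
    lon = runif(fg$n_centers, ext[1] + mx, ext[2] - mx),
    lat = runif(fg$n_centers, ext[3] + my, ext[4] - my)
  )
  fp <- matrix(fg$baseline, nrows, ncols)
  for (i in seq_len(fg$n_centers)) {
    d2 <- (lon_m - centers[i, "lon"])^2 + (lat_m - centers[i, "lat"])^2
    fp <- fp + fg$amplitude * exp(-d2 / (2 * fg$sigma_deg^2))
  }
  footprint <- ascii_grid(fp, ext[1], ext[3], res)

  climate <- ascii_grid(30 - config$climate_lapse * abs(lat_m), ext[1], ext[3], res)

  biomes <- band_polygons(ext, config$n_biomes, horizontal = TRUE, prefix = "biome")
  countries <- band_polygons(ext, config$n_countries, horizontal = FALSE, prefix = "country")

  types <- c("capital", "centroid", "institution")
  radii <- c(capital = 10, centroid = 1, institution = 0.1)
  n_each <- config$n_gazetteer
  gaz_lon <- runif(3 * n_each, ext[1] + mx, ext[2] - mx)
  gaz_lat <- runif(3 * n_each, ext[3] + my, ext[4] - my)
  gaz_type <- rep(types, each = n_each)
  gazetteer <- data.frame(
    name = paste0(gaz_type, "_", rep(seq_len(n_each), times = 3)),
    lon = gaz_lon, lat = gaz_lat,
    radius_km = unname(radii[gaz_type]),
    type = gaz_type,
    stringsAsFactors = FALSE
  )

  reference_layers(
    extent = ext, biomes = biomes, countries = countries,
    footprint = footprint, climate = climate, land = land,
    gazetteer = gazetteer
  )
}

# Uniformly sample n points on land (cell-uniform within random land cells).
sample_land_points <- function(layers, n) {
  g <- layers$land
  land_idx <- which(g$values == 1, arr.ind = TRUE)
  if (!nrow(land_idx)) stop("world has no land cells")
  pick <- land_idx[sample.int(nrow(land_idx), n, replace = TRUE), , drop = FALSE]
  res <- g$cellsize
  lon <- g$xllcorner + (pick[, "col"] - 1 + runif(n)) * res
  lat <- g$yllcorner + (g$nrows - pick[, "row"] + runif(n)) * res
  data.frame(lon = lon, lat = lat)
}

# Uniformly sample n points at sea.
sample_sea_points <- function(layers, n) {
  g <- layers$land
  sea_idx <- which(g$values == 0, arr.ind = TRUE)
  if (!nrow(sea_idx)) stop("world has no sea cells")
  pick <- sea_idx[sample.int(nrow(sea_idx), n, replace = TRUE), , drop = FALSE]
  res <- g$cellsize
  data.frame(
    lon = g$xllcorner + (pick[, "col"] - 1 + runif(n)) * res,
    lat = g$yllcorner + (g$nrows - pick[, "row"] + runif(n)) * res
  )
}
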