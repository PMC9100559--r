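# Cylindrical equal-area projection centered on the point set: standard
# parallel at the mean latitude, central meridian at the mean longitude.
# Returns coordinates in km; exact-area property of the projection makes
# planar polygon/grid areas equal the corresponding spherical areas.
project_equal_area <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  phi_s <- lat0 * pi / 180
  k <- cos(phi_s)
  dlon <- (lon - lon0) * pi / 180
  # wrap to (-pi, pi] so point sets straddling the antimeridian stay compact
  dlon <- ((dlon + pi) %% (2 * pi)) - pi
  list(
    x = EARTH_RADIUS_KM * dlon * k,
    y = EARTH_RADIUS_KM * sin(lat * pi / 180) / k,
    lon0 = lon0, lat0 = lat0
  )
}

# Shoelace formula; absolute planar polygon area.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extent of occurrence (EOO)
#'
#' Area of the convex hull of a species' cleaned records, computed in a
#' cylindrical equal-area projection centered on the points. Undefined
#' (`NA`) with fewer than 3 unique points or when all points are collinear
#' (hull area 0).
#'
#' @param lon,lat Coordinates of one species' cleaned records.
#' @return Hull area in km2, or `NA` if degenerate.
#' @export
compute_eoo <- function(lon, lat) {
  u <- unique(data.frame(lon = lon, lat = lat))
  if (nrow(u) < 3) return(NA_real_)
  if (points_collinear(u$lon, u$lat)) return(NA_real_)
  p <- project_equal_area(u$lon, u$lat)
  h <- chull(p$x, p$y)
  if (length(h) < 3) return(NA_real_)
  a <- shoelace_area(p$x[h], p$y[h])
  if (a <= 0) return(NA_real_)
  a
}

# All points on one straight line in lon/lat space (relative tolerance)?
points_collinear <- function(lon, lat, tol = 1e-9) {
  dx <- lon - lon[1]
  dy <- lat - lat[1]
  scale <- max(abs(c(dx, dy)))
  if (scale == 0) return(TRUE)
  # use the most distant point as the reference direction
  ref <- which.max(dx^2 + dy^2)
  cross <- dx * dy[ref] - dx[ref] * dy
  all(abs(cross) <= tol * scale^2)
}

#' Area of occupancy (AOO)
#'
#' Number of distinct occupied cells of a fixed `cell_km` x `cell_km` grid
#' (IUCN standard: 2 km), times the cell area. The grid lives in the same
#' equal-area projection as the EOO and is anchored at the projection origin
#' with a cell centered on it (so a tight cluster at the origin occupies one
#' cell, not four). AOO is grid-anchor-sensitive by at most one cell per
#' cluster edge.
#'
#' @param lon,lat Coordinates of one species' records (at least one point).
#' @param cell_km Grid cell width in km.
#' @return Occupied area in km2.
#' @export
compute_aoo <- function(lon, lat, cell_km = 2) {
  stopifnot(length(lon) >= 1)
  p <- project_equal_area(lon, lat)
  cells <- unique(paste(
    floor(p$x / cell_km + 0.5), floor(p$y / cell_km + 0.5)
  ))
  length(cells) * cell_km^2
}

#' Latitudinal range
#'
#' @param lat Latitudes of one species' records.
#' @return `max(lat) - min(lat)` in degrees.
#' @export
compute_lat_range <- function(lat) {
  stopifnot(length(lat) >= 1)
  max(lat) - min(lat)
}

#' Biome presence vector
#'
#' @param lon,lat Record coordinates of one species.
#' @param biomes A `polygon_layer` of biomes partitioning the land extent.
#' @return Integer 0/1 vector, one entry per biome: 1 iff at least one record
#'   falls in that biome (boundary points go to the lowest biome id). Records
#'   outside all biomes are counted in the `n_unassigned` attribute.
#' @export
biome_presence <- function(lon, lat, biomes) {
  loc <- locate_in_polygons(biomes, lon, lat)
  pres <- integer(length(biomes))
  hit <- loc[!is.na(loc)]
  pres[unique(hit)] <- 1L
  attr(pres, "n_unassigned") <- sum(is.na(loc))
  pres
}

#' Climate summary at record locations
#'
#' Nearest-cell sampling of the climate raster at each record; missing cells
#' (outside the raster or nodata) are skipped and counted.
#'
#' @param lon,lat Record coordinates.
#' @param raster An `ascii_grid`.
#' @return List with `mean`, `sd` (population sd) and `n_missing`; `mean` and
#'   `sd` are `NA` when no record samples a value.
#' @export
climate_summary <- function(lon, lat, raster) {
  v <- grid_sample(raster, lon, lat)
  ok <- v[!is.na(v)]
  if (!length(ok)) {
    return(list(mean = NA_real_, sd = NA_real_, n_missing = sum(is.na(v))))
  }
  list(
    mean = mean(ok),
    sd = sqrt(mean((ok - mean(ok))^2)),
    n_missing = sum(is.na(v))
  )
}

#' Human-footprint exposure fractions
#'
#' Samples the footprint raster at each record and bins the values into the
#' half-open intervals `[e_k, e_{k+1})` given by `bin_edges`. Fractions are
#' taken over records with a sampled value and sum to 1.
#'
#' @param lon,lat Record coordinates.
#' @param raster Footprint `ascii_grid` (values >= 0).
#' @param bin_edges Strictly increasing edges covering the value range;
#'   default the four footprint pressure categories `(0, 1, 10, 20, Inf)`.
#' @return Numeric fraction vector of length `length(bin_edges) - 1`; all
#'   `NA` when no record samples a value.
#' @export
footprint_features <- function(lon, lat, raster, bin_edges = c(0, 1, 10, 20, Inf)) {
  stopifnot(all(diff(bin_edges) > 0))
  v <- grid_sample(raster, lon, lat)
  ok <- v[!is.na(v)]
  k <- length(bin_edges) - 1
  if (!length(ok)) return(rep(NA_real_, k))
  idx <- findInterval(ok, bin_edges, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > k] <- k
  tabulate(idx, nbins = k) / length(ok)
}

#' Feature-extraction configuration
#'
#' @param aoo_cell_km AOO grid cell width (km).
#' @param footprint_bins Footprint bin edges.
#' @param eoo_fallback When `TRUE`, species with a degenerate hull keep their
#'   AOO as the EOO value instead of being dropped (off by default: species
#'   with incomplete features are omitted).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(aoo_cell_km = 2,
                           footprint_bins = c(0, 1, 10, 20, Inf),
                           eoo_fallback = FALSE) {
  structure(
    list(
      aoo_cell_km = aoo_cell_km, footprint_bins = footprint_bins,
      eoo_fallback = eoo_fallback
    ),
    class = "feature_config"
  )
}

#' Assemble the per-species feature matrix
#'
#' Computes, per species: record count, EOO, AOO, latitudinal range, biome
#' presence bits, climate mean/sd and footprint exposure fractions. Species
#' with any undefined feature are dropped and listed with a reason, unless
#' the EOO fallback is enabled (which only rescues degenerate hulls).
#'
#' @param occurrences Cleaned occurrence data frame.
#' @param layers A [reference_layers()] object.
#' @param config A [feature_config()].
#' @return List of class `feature_set`: `features` (data frame, one row per
#'   retained species, `species` column first plus named feature columns),
#'   `dropped` (data frame `species`, `reason`).
#' @export
assemble_features <- function(occurrences, layers, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  sp_list <- sort(unique(occurrences$species))
  if (!length(sp_list)) stop("no species in cleaned occurrences")
  n_biomes <- length(layers$biomes)
  k_fp <- length(config$footprint_bins) - 1

  rows <- vector("list", length(sp_list))
  dropped <- list()
  for (i in seq_along(sp_list)) {
    sp <- sp_list[i]
    o <- occurrences[occurrences$species == sp, ]
    lon <- o$decimalLongitude
    lat <- o$decimalLatitude
    eoo <- compute_eoo(lon, lat)
    aoo <- compute_aoo(lon, lat, config$aoo_cell_km)
    if (is.na(eoo)) {
      if (config$eoo_fallback) {
        eoo <- aoo
      } else {
        dropped[[length(dropped) + 1]] <- data.frame(
          species = sp, reason = "eoo_undefined", stringsAsFactors = FALSE)
        next
      }
    }
    clim <- climate_summary(lon, lat, layers$climate)
    fp <- footprint_features(lon, lat, layers$footprint, config$footprint_bins)
    if (is.na(clim$mean) || any(is.na(fp))) {
      dropped[[length(dropped) + 1]] <- data.frame(
        species = sp, reason = "raster_unsampled", stringsAsFactors = FALSE)
      next
    }
    bio <- biome_presence(lon, lat, layers$biomes)
    row <- c(
      occ_count = length(lon),
      eoo_km2 = eoo,
      aoo_km2 = aoo,
      lat_range_deg = compute_lat_range(lat),
      setNames(as.numeric(bio), paste0("biome_", seq_len(n_biomes))),
      clim_mean = clim$mean,
      clim_sd = clim$sd,
      setNames(fp, paste0("footprint_", seq_len(k_fp)))
    )
    rows[[i]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no species with complete features")
  mat <- do.call(rbind, rows[keep])
  features <- data.frame(species = sp_list[keep], mat,
    stringsAsFactors = FALSE, row.names = NULL)
  dropped_df <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(species = character(0), reason = character(0))
  }
  structure(list(features = features, dropped = dropped_df),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d species x %d features (%d dropped)\n",
    nrow(x$features), ncol(x$features) - 1, nrow(x$dropped)))
  invisible(x)
}

# Feature columns that are passed through normalization untouched.
is_binary_column <- function(name) grepl("^biome_", name)
# Heavily right-skewed columns get a log10(x + 1) before z-scoring.
is_log_column <- function(name) name %in% c("occ_count", "eoo_km2", "aoo_km2")

#' Normalize a feature matrix
#'
#' Applies `log10(x + 1)` to the count/area columns, then z-scores every
#' non-binary column. When `params` is `NULL` the statistics are computed
#' from the data (training set); passing stored `params` applies the training
#' transform to new rows (prediction set), so no prediction-set statistics
#' ever leak into the model.
#'
#' @param features Feature data frame from [assemble_features()] (with the
#'   `species` column).
#' @param params Normalization parameters from a previous call, or `NULL`.
#' @return List of class `normalized_features`: `features` (normalized data
#'   frame), `params` (per-column transform, mean, sd).
#' @export
normalize_features <- function(features, params = NULL) {
  cols <- setdiff(names(features), "species")
  out <- features
  if (is.null(params)) {
    params <- list(columns = cols, log = is_log_column(cols),
      binary = is_binary_column(cols), mean = numeric(length(cols)),
      sd = numeric(length(cols)))
    for (j in seq_along(cols)) {
      v <- features[[cols[j]]]
      if (params$log[j]) v <- log10(v + 1)
      if (params$binary[j]) {
        params$mean[j] <- 0
        params$sd[j] <- 1
      } else {
        params$mean[j] <- mean(v)
        s <- sqrt(mean((v - mean(v))^2))
        if (s == 0) {
          warning("zero-variance feature column: ", cols[j])
          s <- 1
        }
        params$sd[j] <- s
      }
    }
  }
  if (!identical(params$columns, cols)) {
    stop("feature columns do not match normalization parameters")
  }
  for (j in seq_along(cols)) {
    v <- out[[cols[j]]]
    if (params$log[j]) v <- log10(v + 1)
    if (!params$binary[j]) v <- (v - params$mean[j]) / params$sd[j]
    out[[cols[j]]] <- v
  }
  structure(list(features = out, params = params), class = "normalized_features")
}

#' Invert a feature normalization
#'
#' @param normalized Normalized feature data frame.
#' @param params Parameters returned by [normalize_features()].
#' @return Data frame on the raw feature scale.
#' @export
denormalize_features <- function(normalized, params) {
  cols <- params$columns
  out <- normalized
  for (j in seq_along(cols)) {
    v <- out[[cols[j]]]
    if (!params$binary[j]) v <- v * params$sd[j] + params$mean[j]
    if (params$log[j]) v <- 10^v - 1
    out[[cols[j]]] <- v
  }
  out
}

#' Write normalization parameters as JSON
#'
#' @param params Parameters from [normalize_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalization_params <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Numeric feature matrix (drops the species column).
feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "species"), drop = FALSE])
}
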