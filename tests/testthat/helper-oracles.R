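# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances use an explicit haversine formula,
# point-in-polygon is ray casting, areas go through geosphere's geodesic
# polygon area, and grid/bin lookups are re-derived loops.

oracle_haversine_km <- function(lon1, lat1, lon2, lat2, r = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Ray casting: odd number of crossings of a rightward ray = inside.
oracle_point_in_ring <- function(ring, lon, lat) {
  n <- nrow(ring)
  xs <- ring$lon
  ys <- ring$lat
  inside <- logical(length(lon))
  for (p in seq_along(lon)) {
    x <- lon[p]
    y <- lat[p]
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        if (x < xint) cross <- !cross
      }
      j <- i
    }
    inside[p] <- cross
  }
  inside
}

# Geodesic area (km2) of the convex hull of a point set, via geosphere
# (WGS84 geodesic polygon area). The hull is a polygon with straight edges
# in the cylindrical equal-area plane; its boundary is densified before the
# geodesic computation so both routes measure the same region and only the
# area computation differs.
oracle_hull_area_km2 <- function(lon, lat, r = 6371.0088, n_seg = 64) {
  u <- unique(data.frame(lon = lon, lat = lat))
  lon0 <- mean(u$lon)
  lat0 <- mean(u$lat)
  k <- cos(lat0 * pi / 180)
  x <- r * (((u$lon - lon0) * pi / 180 + pi) %% (2 * pi) - pi) * k
  y <- r * sin(u$lat * pi / 180) / k
  h <- grDevices::chull(x, y)
  hx <- x[h]
  hy <- y[h]
  dense_x <- dense_y <- numeric(0)
  for (i in seq_along(h)) {
    j <- if (i == length(h)) 1 else i + 1
    t <- seq(0, 1, length.out = n_seg + 1)[-(n_seg + 1)]
    dense_x <- c(dense_x, hx[i] + t * (hx[j] - hx[i]))
    dense_y <- c(dense_y, hy[i] + t * (hy[j] - hy[i]))
  }
  dense_lon <- lon0 + dense_x / (r * k) * 180 / pi
  dense_lat <- asin(pmin(1, pmax(-1, dense_y * k / r))) * 180 / pi
  geosphere::areaPolygon(cbind(dense_lon, dense_lat)) / 1e6
}

# Brute-force AOO: independent cylindrical equal-area formula, explicit
# cell-index set. Same standard parallel / anchor convention as the package
# (a cell is centered on the projection origin).
oracle_aoo_km2 <- function(lon, lat, cell_km = 2, r = 6371.0088) {
  lon0 <- mean(lon)
  lat0 <- mean(lat)
  k <- cos(lat0 * pi / 180)
  dlon <- ((lon - lon0) * pi / 180 + pi) %% (2 * pi) - pi
  x <- r * dlon * k
  y <- r * sin(lat * pi / 180) / k
  keys <- character(0)
  for (i in seq_along(x)) {
    keys <- c(keys, paste(
      floor(x[i] / cell_km + 0.5), floor(y[i] / cell_km + 0.5)
    ))
  }
  length(unique(keys)) * cell_km^2
}

# Direct nearest-cell raster lookup (independent of grid_sample).
oracle_grid_lookup <- function(grid, lon, lat) {
  out <- numeric(length(lon))
  for (i in seq_along(lon)) {
    col <- floor((lon[i] - grid$xllcorner) / grid$cellsize) + 1
    row <- grid$nrows - floor((lat[i] - grid$yllcorner) / grid$cellsize)
    if (col >= 1 && col <= grid$ncols && row >= 1 && row <= grid$nrows) {
      out[i] <- grid$values[row, col]
    } else {
      out[i] <- NA_real_
    }
  }
  out
}

# Exhaustive threshold search: smallest observed confidence whose retained
# set meets the target accuracy.
oracle_find_threshold <- function(confidence, correct, target) {
  best <- NA_real_
  for (t in sort(unique(confidence))) {
    if (mean(correct[confidence >= t]) >= target) {
      best <- t
      break
    }
  }
  best
}

# Shoelace polygon area on lon/lat degrees scaled to km at a reference
# latitude (adequate for the small band polygons of toy worlds).
oracle_band_area_km2 <- function(ring) {
  # exact spherical area for lon/lat-aligned rectangles
  r <- 6371.0088
  lam <- range(ring$lon) * pi / 180
  phi <- range(ring$lat) * pi / 180
  r^2 * (lam[2] - lam[1]) * (sin(phi[2]) - sin(phi[1]))
}

# Small world used by most tests: 40 x 40 degree square, 4 biomes, 4
# countries, 1-degree cells.
make_test_world <- function(seed = 7, n_biomes = 4, n_countries = 4) {
  generate_world(world_config(
    extent = c(-20, 20, -20, 20), n_biomes = n_biomes,
    n_countries = n_countries, raster_resolution_deg = 1, seed = seed
  ))
}

# Quick labeled feature simulation for model tests: two Gaussian clusters
# in d dimensions separated by `margin` standard deviations, columns then
# z-scored as the feature pipeline would deliver them.
make_cluster_data <- function(n_per_class, d = 5, margin = 6, classes = c(0L, 1L),
                              seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(rnorm(n_per_class * d, mean = (i - 1) * margin), n_per_class, d)
  }))
  x <- scale(x)
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  y <- rep(classes, each = n_per_class)
  ord <- sample(length(y))
  list(x = x[ord, , drop = FALSE], y = y[ord])
}
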