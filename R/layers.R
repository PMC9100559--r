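#' @importFrom stats quantile rbinom rlnorm rnorm runif sd setNames rbeta aggregate cor
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
NULL

# Mean Earth radius (km), IUGG value; used for all local projections.
EARTH_RADIUS_KM <- 6371.0088

#' Create a plain-text raster grid
#'
#' A minimal raster container mirroring the ESRI ASCII grid layout: a regular
#' lon/lat cell grid with the value matrix stored north-to-south (row 1 is the
#' northernmost row).
#'
#' @param values Numeric matrix, `nrows x ncols`, row 1 = top (max latitude).
#' @param xllcorner,yllcorner Lon/lat of the lower-left corner of the grid.
#' @param cellsize Cell size in decimal degrees (square cells).
#' @param nodata Value standing in for missing cells in the text encoding.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xllcorner, yllcorner, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(
      ncols = ncol(values), nrows = nrow(values),
      xllcorner = xllcorner, yllcorner = yllcorner,
      cellsize = cellsize, nodata = nodata, values = values
    ),
    class = "ascii_grid"
  )
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf(
    "<ascii_grid> %d x %d cells, %.4f deg, origin (%.3f, %.3f)\n",
    x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner
  ))
  invisible(x)
}

#' Write a grid as an ESRI ASCII raster file
#'
#' @param grid An `ascii_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  rows <- apply(vals, 1L, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster file
#'
#' @param path File path.
#' @return An `ascii_grid`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- matrix(
    scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
    nrow = h[["nrows"]], byrow = TRUE
  )
  vals[vals == h[["nodata_value"]]] <- NA
  ascii_grid(vals, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
    nodata = h[["nodata_value"]]
  )
}

#' Sample a grid at point locations (nearest cell)
#'
#' @param grid An `ascii_grid`.
#' @param lon,lat Numeric vectors of coordinates (decimal degrees).
#' @return Numeric vector of cell values; `NA` for points outside the grid.
#' @export
grid_sample <- function(grid, lon, lat) {
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1L
  row <- grid$nrows - floor((lat - grid$yllcorner) / grid$cellsize)
  # points exactly on the top/right edge belong to the outermost cell
  col[lon == grid$xllcorner + grid$ncols * grid$cellsize] <- grid$ncols
  row[lat == grid$yllcorner + grid$nrows * grid$cellsize] <- 1L
  ok <- col >= 1L & col <= grid$ncols & row >= 1L & row <= grid$nrows &
    !is.na(col) & !is.na(row)
  out <- rep(NA_real_, length(lon))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Build a polygon layer from rings
#'
#' @param ids Integer or character ids, one per polygon.
#' @param names Character names, one per polygon.
#' @param rings List of data frames with columns `lon`, `lat`; each ring is
#'   closed implicitly (last vertex need not repeat the first).
#' @return An object of class `polygon_layer`.
#' @export
polygon_layer <- function(ids, names, rings) {
  stopifnot(length(ids) == length(rings), length(names) == length(rings))
  structure(list(id = ids, name = names, rings = rings), class = "polygon_layer")
}

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("<polygon_layer> %d polygons: %s\n", length(x$id),
    paste(head(x$name, 5), collapse = ", ")))
  invisible(x)
}

#' @export
length.polygon_layer <- function(x) length(x$id)

#' Write a polygon layer to GeoJSON
#'
#' @param layer A `polygon_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(layer, path) {
  feats <- lapply(seq_along(layer$id), function(i) {
    ring <- layer$rings[[i]]
    # close the ring explicitly, per GeoJSON
    if (ring$lon[1] != ring$lon[nrow(ring)] || ring$lat[1] != ring$lat[nrow(ring)]) {
      ring <- rbind(ring, ring[1, ])
    }
    list(
      type = "Feature",
      properties = list(id = layer$id[i], name = layer$name[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(unname(as.matrix(ring[, c("lon", "lat")])))
      )
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' Supports the simple single-ring polygons written by
#' [write_polygons_geojson()].
#'
#' @param path GeoJSON file path.
#' @return A `polygon_layer`.
#' @export
read_polygons_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  rings <- lapply(feats, function(f) {
    coords <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    data.frame(lon = m[, 1], lat = m[, 2])
  })
  polygon_layer(
    ids = vapply(feats, function(f) f$properties$id, numeric(1)),
    names = vapply(feats, function(f) as.character(f$properties$name), character(1)),
    rings = rings
  )
}

#' Test points against the polygons of a layer
#'
#' Each point is assigned to the first polygon (in id order) that contains it,
#' so points on shared boundaries go to the lowest-id polygon.
#'
#' @param layer A `polygon_layer`.
#' @param lon,lat Point coordinates.
#' @return Integer vector of polygon indices (`NA` = in no polygon).
#' @export
locate_in_polygons <- function(layer, lon, lat) {
  ord <- order(layer$id)
  out <- rep(NA_integer_, length(lon))
  pts <- cbind(lon, lat)
  for (i in ord) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    ring <- layer$rings[[i]]
    inside <- mgcv::in.out(as.matrix(ring[, c("lon", "lat")]), pts[todo, , drop = FALSE])
    out[todo[inside]] <- i
  }
  out
}

#' Bundle toy reference layers
#'
#' @param extent Named numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param biomes,countries `polygon_layer`s partitioning the extent.
#' @param footprint,climate,land `ascii_grid`s (land: 1 = land, 0 = sea).
#' @param gazetteer Data frame with columns `name`, `lon`, `lat`, `radius_km`,
#'   `type`.
#' @return An object of class `reference_layers`.
#' @export
reference_layers <- function(extent, biomes, countries, footprint, climate,
                             land, gazetteer) {
  structure(
    list(
      extent = extent, biomes = biomes, countries = countries,
      footprint = footprint, climate = climate, land = land,
      gazetteer = gazetteer
    ),
    class = "reference_layers"
  )
}

#' @export
print.reference_layers <- function(x, ...) {
  cat(sprintf(
    "<reference_layers> extent [%g, %g] x [%g, %g]; %d biomes, %d countries, %d gazetteer entries\n",
    x$extent[1], x$extent[2], x$extent[3], x$extent[4],
    length(x$biomes), length(x$countries), nrow(x$gazetteer)
  ))
  invisible(x)
}

#' Write reference layers to a directory of plain-text files
#'
#' Biome and country polygons as GeoJSON, rasters as ASCII grids, the
#' gazetteer as CSV, plus a small JSON manifest with the extent.
#'
#' @param layers A `reference_layers` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_layers <- function(layers, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_polygons_geojson(layers$biomes, file.path(dir, "biomes.geojson"))
  write_polygons_geojson(layers$countries, file.path(dir, "countries.geojson"))
  write_ascii_grid(layers$footprint, file.path(dir, "footprint.asc"))
  write_ascii_grid(layers$climate, file.path(dir, "climate.asc"))
  write_ascii_grid(layers$land, file.path(dir, "land.asc"))
  write.csv(layers$gazetteer, file.path(dir, "gazetteer.csv"), row.names = FALSE)
  jsonlite::write_json(list(extent = layers$extent), file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read reference layers from a directory written by [write_layers()]
#'
#' @param dir Directory path.
#' @return A `reference_layers` object.
#' @export
read_layers <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  reference_layers(
    extent = man$extent,
    biomes = read_polygons_geojson(file.path(dir, "biomes.geojson")),
    countries = read_polygons_geojson(file.path(dir, "countries.geojson")),
    footprint = read_ascii_grid(file.path(dir, "footprint.asc")),
    climate = read_ascii_grid(file.path(dir, "climate.asc")),
    land = read_ascii_grid(file.path(dir, "land.asc")),
    gazetteer = read.csv(file.path(dir, "gazetteer.csv"), stringsAsFactors = FALSE)
  )
}
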