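# Class-dependent generator settings. Medians follow the assumption that Red
# List criteria reflect range size and population size: more threatened
# species get smaller ranges, fewer records and higher human-footprint
# exposure. Chosen once; see the methods vignette.
SPECIES_CLASS_PARAMS <- list(
  radius_median_km = c(LC = 500, NT = 200, VU = 80, EN = 30, CR = 10),
  radius_sdlog = 0.6,
  records_median = c(LC = 80, NT = 50, VU = 30, EN = 15, CR = 8),
  records_sdlog = 0.7,
  footprint_affinity_mean = c(LC = 0.3, NT = 0.4, VU = 0.5, EN = 0.6, CR = 0.7),
  footprint_affinity_conc = 10
)

# Default class mix = the Red List label proportions of the labeled tree flora
# (LC-heavy, thin NT).
DEFAULT_CLASS_MIX <- c(LC = 0.536, NT = 0.064, VU = 0.159, EN = 0.159, CR = 0.082)

#' Generate species with known threat-dependent range structure
#'
#' Each species draws a true Red List class from `class_mix`, then a range
#' radius and a record count from class-specific log-normal distributions
#' (stochastically decreasing with threat severity) and a footprint affinity
#' from a class-specific beta distribution. Range centers are placed on land;
#' higher footprint affinity biases the center toward high-footprint cells.
#'
#' @param n_species Number of species (0 allowed, giving an empty table).
#' @param class_mix Probability vector over `c("LC","NT","VU","EN","CR")`,
#'   summing to 1.
#' @param world A [reference_layers()] object.
#' @param seed Integer RNG seed.
#' @return Data frame with one row per species: `species`, `true_class`,
#'   `center_lon`, `center_lat`, `range_radius_km`, `n_records`,
#'   `footprint_affinity`.
#' @export
generate_species <- function(n_species, class_mix = DEFAULT_CLASS_MIX, world,
                             seed = 1L) {
  stopifnot(inherits(world, "reference_layers"), n_species >= 0)
  class_mix <- as.numeric(class_mix)
  if (length(class_mix) != 5 || any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be 5 non-negative probabilities summing to 1")
  }
  empty <- data.frame(
    species = character(0), true_class = character(0),
    center_lon = numeric(0), center_lat = numeric(0),
    range_radius_km = numeric(0), n_records = integer(0),
    footprint_affinity = numeric(0), stringsAsFactors = FALSE
  )
  if (n_species == 0) return(empty)
  set.seed(seed)
  p <- SPECIES_CLASS_PARAMS
  cls <- sample(RL_CLASSES, n_species, replace = TRUE, prob = class_mix)
  radius <- rlnorm(n_species, log(p$radius_median_km[cls]), p$radius_sdlog)
  n_rec <- pmax(1L, as.integer(round(
    rlnorm(n_species, log(p$records_median[cls]), p$records_sdlog)
  )))
  a <- p$footprint_affinity_mean[cls] * p$footprint_affinity_conc
  b <- (1 - p$footprint_affinity_mean[cls]) * p$footprint_affinity_conc
  affinity <- rbeta(n_species, a, b)

  # Center placement: 25 candidate land points per species; pick the
  # candidate at the footprint quantile given by the species' affinity.
  n_cand <- 25L
  cand <- sample_land_points(world, n_species * n_cand)
  fp <- grid_sample(world$footprint, cand$lon, cand$lat)
  idx <- matrix(seq_len(n_species * n_cand), nrow = n_cand)
  center <- vapply(seq_len(n_species), function(i) {
    ii <- idx[, i]
    ord <- ii[order(fp[ii])]
    pick <- ord[1L + floor(affinity[i] * (n_cand - 1L) + 0.5)]
    c(cand$lon[pick], cand$lat[pick])
  }, numeric(2))

  data.frame(
    species = sprintf("species_%04d", seq_len(n_species)),
    true_class = cls,
    center_lon = center[1, ], center_lat = center[2, ],
    range_radius_km = unname(radius),
    n_records = n_rec,
    footprint_affinity = unname(affinity),
    stringsAsFactors = FALSE
  )
}

#' Contamination configuration for the occurrence generator
#'
#' Rates of the error classes found in raw aggregated occurrence data: the
#' 0/0 point, transposed/equal coordinates, points at sea, points on
#' capitals/centroids/institutions (gazetteer hits), excessive coordinate
#' uncertainty, exact duplicates, far-displaced spatial outliers, and
#' disallowed basis-of-record values. Each record receives at most one error.
#'
#' @param zero_zero,lat_eq_lon,sea_point,gazetteer_hit,high_uncertainty,duplicate,spatial_outlier,bad_basis
#'   Proportions in `[0, 1]`; their sum must be `<= 1`.
#' @param seed Integer RNG seed used when injecting errors.
#' @return A list of class `contamination_config`.
#' @export
contamination_config <- function(zero_zero = 0, lat_eq_lon = 0, sea_point = 0,
                                 gazetteer_hit = 0, high_uncertainty = 0,
                                 duplicate = 0, spatial_outlier = 0,
                                 bad_basis = 0, seed = 1L) {
  rates <- c(
    zero_zero = zero_zero, lat_eq_lon = lat_eq_lon, sea_point = sea_point,
    gazetteer_hit = gazetteer_hit, high_uncertainty = high_uncertainty,
    duplicate = duplicate, spatial_outlier = spatial_outlier,
    bad_basis = bad_basis
  )
  if (any(rates < 0) || any(rates > 1)) stop("contamination rates must lie in [0, 1]")
  if (sum(rates) > 1 + 1e-12) stop("contamination rates must sum to <= 1")
  structure(list(rates = rates, seed = as.integer(seed)),
    class = "contamination_config"
  )
}

#' Default contamination mix for end-to-end runs
#'
#' A moderate error load (12% of records) spread over the eight error classes.
#'
#' @param seed Integer RNG seed.
#' @return A [contamination_config()].
#' @export
default_contamination <- function(seed = 1L) {
  contamination_config(
    zero_zero = 0.01, lat_eq_lon = 0.01, sea_point = 0.02,
    gazetteer_hit = 0.01, high_uncertainty = 0.02, duplicate = 0.03,
    spatial_outlier = 0.01, bad_basis = 0.01, seed = seed
  )
}

# Local tangent-plane offsets (km) -> lon/lat around a center.
offset_lonlat <- function(lon0, lat0, dx_km, dy_km) {
  lat <- lat0 + dy_km / 111.32
  lon <- lon0 + dx_km / (111.32 * cos(lat0 * pi / 180))
  data.frame(lon = lon, lat = lat)
}

# Draw n points around a center: isotropic Gaussian (sd = radius/2) on the
# local tangent plane, truncated at the range radius, rejected into land.
draw_range_points <- function(world, lon0, lat0, radius_km, n) {
  out_lon <- numeric(n)
  out_lat <- numeric(n)
  need <- seq_len(n)
  for (tries in 1:40) {
    m <- length(need)
    if (!m) break
    r <- abs(rnorm(m, 0, radius_km / 2))
    r <- pmin(r, radius_km * 0.999)
    th <- runif(m, 0, 2 * pi)
    p <- offset_lonlat(lon0, lat0, r * cos(th), r * sin(th))
    land_val <- grid_sample(world$land, p$lon, p$lat)
    ok <- which(!is.na(land_val) & land_val == 1)
    if (length(ok)) {
      out_lon[need[ok]] <- p$lon[ok]
      out_lat[need[ok]] <- p$lat[ok]
      need <- need[-ok]
    } else if (tries > 5) {
      break
    }
  }
  if (length(need)) { # fall back to the center itself (known to be on land)
    jit <- offset_lonlat(lon0, lat0, runif(length(need), -0.5, 0.5),
      runif(length(need), -0.5, 0.5))
    out_lon[need] <- jit$lon
    out_lat[need] <- jit$lat
  }
  data.frame(lon = out_lon, lat = out_lat)
}

#' Generate a contaminated occurrence table with a truth sidecar
#'
#' Draws `n_records` clean points per species within its range radius, then
#' injects errors at the configured rates. The returned occurrence table
#' carries Darwin-Core-style columns only; the per-record error type (and the
#' species' true class) live in a separate sidecar so they can never leak
#' into the pipeline under test.
#'
#' @param species Data frame from [generate_species()] (non-empty).
#' @param world A [reference_layers()] object.
#' @param contamination A [contamination_config()].
#' @return List with `occurrences` (columns `record_id`, `species`,
#'   `decimalLongitude`, `decimalLatitude`, `coordinateUncertaintyInMeters`,
#'   `basisOfRecord`) and `truth` (`record_id`, `species`, `error`).
#' @export
generate_occurrences <- function(species, world,
                                 contamination = contamination_config()) {
  stopifnot(inherits(world, "reference_layers"),
    inherits(contamination, "contamination_config"))
  if (!nrow(species)) stop("species table must be non-empty")
  set.seed(contamination$seed)

  n_tot <- sum(species$n_records)
  sp_idx <- rep(seq_len(nrow(species)), species$n_records)
  pts <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    draw_range_points(world, species$center_lon[i], species$center_lat[i],
      species$range_radius_km[i], species$n_records[i])
  }))

  allowed_bases <- c("HUMAN_OBSERVATION", "PRESERVED_SPECIMEN", "LITERATURE")
  basis <- sample(allowed_bases, n_tot, replace = TRUE, prob = c(0.7, 0.25, 0.05))
  unc <- rlnorm(n_tot, log(3000), 1)
  unc <- pmin(unc, 99000)
  unc[runif(n_tot) < 0.15] <- NA # GBIF records commonly omit uncertainty

  occ <- data.frame(
    record_id = sprintf("r%07d", seq_len(n_tot)),
    species = species$species[sp_idx],
    decimalLongitude = pts$lon,
    decimalLatitude = pts$lat,
    coordinateUncertaintyInMeters = unc,
    basisOfRecord = basis,
    stringsAsFactors = FALSE
  )

  rates <- contamination$rates
  err_levels <- c(names(rates), "none")
  error <- sample(err_levels, n_tot, replace = TRUE,
    prob = c(rates, 1 - sum(rates)))

  i <- which(error == "zero_zero")
  occ$decimalLongitude[i] <- 0
  occ$decimalLatitude[i] <- 0

  i <- which(error == "lat_eq_lon")
  occ$decimalLatitude[i] <- occ$decimalLongitude[i]

  i <- which(error == "sea_point")
  if (length(i)) {
    sp <- sample_sea_points(world, length(i))
    occ$decimalLongitude[i] <- sp$lon
    occ$decimalLatitude[i] <- sp$lat
  }

  i <- which(error == "gazetteer_hit")
  if (length(i)) {
    g <- world$gazetteer[sample.int(nrow(world$gazetteer), length(i), replace = TRUE), ]
    r <- g$radius_km * sqrt(runif(length(i))) * 0.9
    th <- runif(length(i), 0, 2 * pi)
    p <- offset_lonlat(g$lon, g$lat, r * cos(th), r * sin(th))
    occ$decimalLongitude[i] <- p$lon
    occ$decimalLatitude[i] <- p$lat
  }

  i <- which(error == "high_uncertainty")
  occ$coordinateUncertaintyInMeters[i] <- runif(length(i), 150000, 1e6)

  i <- which(error == "spatial_outlier")
  if (length(i)) {
    far <- sample_land_points(world, length(i))
    occ$decimalLongitude[i] <- far$lon
    occ$decimalLatitude[i] <- far$lat
  }

  i <- which(error == "bad_basis")
  occ$basisOfRecord[i] <- sample(
    c("FOSSIL_SPECIMEN", "LIVING_SPECIMEN", "UNKNOWN"),
    length(i), replace = TRUE
  )

  # duplicates copy a clean record of the same species (full row copy);
  # demoted to "none" when the species has no clean record to copy
  i <- which(error == "duplicate")
  for (j in i) {
    pool <- which(occ$species == occ$species[j] & error == "none")
    if (!length(pool)) {
      error[j] <- "none"
      next
    }
    src <- if (length(pool) == 1) pool else sample(pool, 1)
    occ$decimalLongitude[j] <- occ$decimalLongitude[src]
    occ$decimalLatitude[j] <- occ$decimalLatitude[src]
    occ$coordinateUncertaintyInMeters[j] <- occ$coordinateUncertaintyInMeters[src]
    occ$basisOfRecord[j] <- occ$basisOfRecord[src]
  }

  list(
    occurrences = occ,
    truth = data.frame(
      record_id = occ$record_id, species = occ$species, error = error,
      stringsAsFactors = FALSE
    )
  )
}

#' Derive label and taxonomy tables for a synthetic species set
#'
#' Emulates the partially assessed Red List: each species is labeled with its
#' true class with probability `label_fraction`; a further `dd_fraction` of
#' the labeled ones are downgraded to DD (Data Deficient). The taxonomy packs
#' species into genera, families and orders of geometric sizes.
#'
#' @param species Data frame from [generate_species()].
#' @param label_fraction Probability that a species carries an RL label.
#' @param dd_fraction Fraction of labeled species recorded as DD.
#' @param n_families,n_orders Taxonomy sizes.
#' @param seed Integer RNG seed.
#' @return List with `labels` (`species`, `category`) and `taxonomy`
#'   (`species`, `genus`, `family`, `order`).
#' @export
generate_labels <- function(species, label_fraction = 0.55, dd_fraction = 0.07,
                            n_families = 20, n_orders = 8, seed = 1L) {
  set.seed(seed)
  n <- nrow(species)
  labeled <- runif(n) < label_fraction
  cat_ <- ifelse(labeled, species$true_class, NA_character_)
  dd <- labeled & runif(n) < dd_fraction
  cat_[dd] <- "DD"
  labels <- data.frame(
    species = species$species[!is.na(cat_)],
    category = cat_[!is.na(cat_)],
    stringsAsFactors = FALSE
  )
  genus <- paste0("genus_", sample.int(max(1, round(n / 4)), n, replace = TRUE))
  family <- paste0("family_", sample.int(n_families, n, replace = TRUE))
  order_ <- paste0(
    "order_",
    match(family, unique(family)) %% n_orders + 1
  )
  taxonomy <- data.frame(
    species = species$species, genus = genus, family = family, order = order_,
    stringsAsFactors = FALSE
  )
  list(labels = labels, taxonomy = taxonomy)
}

#' Write an occurrence table (Darwin-Core-style CSV)
#'
#' @param occurrences Occurrence data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  write.csv(occurrences, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an occurrence table written by [write_occurrences()]
#'
#' @param path CSV path.
#' @return Occurrence data frame.
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path, stringsAsFactors = FALSE,
    colClasses = c(record_id = "character", species = "character"))
  occ$coordinateUncertaintyInMeters <-
    as.numeric(occ$coordinateUncertaintyInMeters)
  occ
}
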