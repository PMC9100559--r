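#' Quality-control configuration for occurrence cleaning
#'
#' Parameters of the record-cleaning cascade: which basis-of-record values are
#' acceptable evidence, the maximum tolerated coordinate uncertainty (records
#' must be *below* it; 100 km by default), the duplicate coordinate precision,
#' the tolerance for the 0/0 test, the gazetteer exclusion radii per location
#' type, and the spatial-outlier rule (minimum-neighbour-distance above
#' Q3 + multiplier * IQR, only applied to species with at least `min_records`
#' records).
#'
#' @param allowed_bases Character set of acceptable `basisOfRecord` values.
#' @param max_uncertainty_m Records survive iff uncertainty `<` this (meters).
#' @param keep_missing_uncertainty Keep records with no stated uncertainty
#'   (default `TRUE`; set `FALSE` for a strict mode that drops them).
#' @param dup_precision Decimal places for the duplicate coordinate key.
#' @param zero_eps Degree tolerance of the 0/0 test.
#' @param gazetteer_radii Named vector of exclusion radii (km) per gazetteer
#'   type, overriding the radii stored in the gazetteer itself.
#' @param outlier_multiplier IQR multiplier of the spatial-outlier rule.
#' @param min_records Minimum conspecific records for the outlier test.
#' @param steps Ordered subset of
#'   `c("basis", "uncertainty", "duplicates", "coordinates", "outliers")`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(allowed_bases = c(
                        "HUMAN_OBSERVATION", "PRESERVED_SPECIMEN", "LITERATURE"
                      ),
                      max_uncertainty_m = 100000,
                      keep_missing_uncertainty = TRUE,
                      dup_precision = 6,
                      zero_eps = 1e-5,
                      gazetteer_radii = c(capital = 10, centroid = 1, institution = 0.1),
                      outlier_multiplier = 5,
                      min_records = 7,
                      steps = c("basis", "uncertainty", "duplicates",
                                "coordinates", "outliers")) {
  if (max_uncertainty_m <= 0) stop("max_uncertainty_m must be > 0")
  if (outlier_multiplier <= 0) stop("outlier_multiplier must be > 0")
  bad <- setdiff(steps, c("basis", "uncertainty", "duplicates", "coordinates", "outliers"))
  if (length(bad)) stop("unknown QC steps: ", paste(bad, collapse = ", "))
  structure(
    list(
      allowed_bases = allowed_bases,
      max_uncertainty_m = max_uncertainty_m,
      keep_missing_uncertainty = keep_missing_uncertainty,
      dup_precision = dup_precision,
      zero_eps = zero_eps,
      gazetteer_radii = gazetteer_radii,
      outlier_multiplier = outlier_multiplier,
      min_records = min_records,
      steps = steps
    ),
    class = "qc_config"
  )
}

#' Filter records by basis of record
#'
#' @param records Occurrence data frame.
#' @param allowed_bases Character vector of acceptable values; anything else
#'   (including unknown strings) is dropped.
#' @return Records whose `basisOfRecord` is allowed, input order preserved.
#' @export
filter_basis <- function(records, allowed_bases) {
  keep <- records$basisOfRecord %in% allowed_bases
  records[keep, , drop = FALSE]
}

#' Filter records by coordinate uncertainty
#'
#' Records survive iff their uncertainty is strictly below the threshold.
#' Missing uncertainty is kept unless `keep_missing = FALSE`; negative values
#' are treated as malformed and dropped.
#'
#' @param records Occurrence data frame.
#' @param max_uncertainty_m Threshold in meters (strict `<`).
#' @param keep_missing Keep records without a stated uncertainty?
#' @return Surviving records, input order preserved.
#' @export
filter_uncertainty <- function(records, max_uncertainty_m, keep_missing = TRUE) {
  u <- records$coordinateUncertaintyInMeters
  keep <- ifelse(is.na(u), keep_missing, u >= 0 & u < max_uncertainty_m)
  records[keep, , drop = FALSE]
}

#' Remove duplicate records
#'
#' At most one record per (species, lon, lat) key survives, coordinates
#' rounded to `precision` decimals; the first record in input order is kept.
#'
#' @param records Occurrence data frame.
#' @param precision Decimal places of the coordinate key.
#' @return De-duplicated records.
#' @export
remove_duplicates <- function(records, precision = 6) {
  key <- paste(
    records$species,
    sprintf("%.*f", precision, records$decimalLongitude),
    sprintf("%.*f", precision, records$decimalLatitude),
    sep = "|"
  )
  records[!duplicated(key), , drop = FALSE]
}

#' Flag suspicious coordinates
#'
#' Applies the coordinate-level tests: the 0/0 point, latitude equal to
#' longitude, points at sea (per the land mask), and points within the
#' exclusion radius of a gazetteer entry (capitals, country centroids,
#' institutions). Each record gets at most one flag, assigned in that order.
#'
#' @param records Occurrence data frame.
#' @param layers A [reference_layers()] object (may lack `land`/`gazetteer`,
#'   in which case those tests are skipped with a warning).
#' @param config A [qc_config()].
#' @return `records` with an added `qc_flag` column
#'   (`"none"`, `"zero_zero"`, `"lat_eq_lon"`, `"sea"`, `"gazetteer"`).
#' @export
flag_coordinate_issues <- function(records, layers, config = qc_config()) {
  n <- nrow(records)
  flag <- rep("none", n)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  eps <- config$zero_eps

  flag[abs(lon) <= eps & abs(lat) <= eps] <- "zero_zero"

  prec <- config$dup_precision
  same <- round(lon, prec) == round(lat, prec)
  flag[flag == "none" & same] <- "lat_eq_lon"

  if (!is.null(layers$land)) {
    land_val <- grid_sample(layers$land, lon, lat)
    at_sea <- !is.na(land_val) & land_val == 0
    flag[flag == "none" & at_sea] <- "sea"
  } else {
    warning("no land mask supplied; sea test skipped")
  }

  gaz <- layers$gazetteer
  if (!is.null(gaz) && nrow(gaz)) {
    radius <- gaz$radius_km
    override <- config$gazetteer_radii[gaz$type]
    radius[!is.na(override)] <- override[!is.na(override)]
    todo <- which(flag == "none")
    for (g in seq_len(nrow(gaz))) {
      if (!length(todo)) break
      d <- geosphere::distHaversine(
        cbind(lon[todo], lat[todo]), c(gaz$lon[g], gaz$lat[g])
      ) / 1000
      hit <- d < radius[g]
      flag[todo[hit]] <- "gazetteer"
      todo <- todo[!hit]
    }
  } else if (is.null(gaz)) {
    warning("no gazetteer supplied; gazetteer test skipped")
  }

  records$qc_flag <- flag
  records
}

#' Flag spatial outliers within one species
#'
#' Computes each record's minimum great-circle distance to any other record
#' of the same species and flags records where this distance exceeds
#' Q3 + `multiplier` * IQR of those minimum distances. Species with fewer
#' than `min_records` records are returned unflagged. Single pass (no
#' iteration to a fixpoint).
#'
#' @param records Occurrence data frame of one species.
#' @param multiplier IQR multiplier.
#' @param min_records Minimum records for the test to run.
#' @return Logical vector, `TRUE` = outlier.
#' @export
flag_spatial_outliers <- function(records, multiplier = 5, min_records = 7) {
  n <- nrow(records)
  if (n < min_records) return(rep(FALSE, n))
  pts <- cbind(records$decimalLongitude, records$decimalLatitude)
  dm <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  diag(dm) <- Inf
  min_nn <- apply(dm, 1, min)
  q <- quantile(min_nn, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  min_nn > q[2] + multiplier * iqr
}

#' Clean an occurrence table
#'
#' Runs the configured cleaning cascade (default order: basis of record,
#' coordinate uncertainty, duplicates, coordinate issues, spatial outliers)
#' and returns the surviving records with a bookkeeping report whose counts
#' always reconcile: input minus the per-step removals equals output.
#'
#' @param records Raw occurrence data frame.
#' @param layers A [reference_layers()] object.
#' @param config A [qc_config()].
#' @return List of class `qc_result` with `records` (cleaned) and `report`
#'   (class `qc_report`): per-step removal counts, coordinate-flag reasons,
#'   input/output totals, per-species surviving counts, missing-uncertainty
#'   count and a config hash.
#' @export
clean <- function(records, layers, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  n_input <- nrow(records)
  removals <- setNames(integer(length(config$steps)), config$steps)
  reasons <- c(zero_zero = 0L, lat_eq_lon = 0L, sea = 0L, gazetteer = 0L)
  n_missing_unc <- sum(is.na(records$coordinateUncertaintyInMeters))
  known_bases <- c(
    "HUMAN_OBSERVATION", "PRESERVED_SPECIMEN", "LITERATURE",
    "FOSSIL_SPECIMEN", "LIVING_SPECIMEN", "UNKNOWN"
  )
  n_unknown_basis <- sum(!records$basisOfRecord %in% known_bases)
  u <- records$coordinateUncertaintyInMeters
  n_malformed_unc <- sum(!is.na(u) & u < 0)

  for (step in config$steps) {
    before <- nrow(records)
    if (step == "basis") {
      records <- filter_basis(records, config$allowed_bases)
    } else if (step == "uncertainty") {
      records <- filter_uncertainty(records, config$max_uncertainty_m,
        keep_missing = config$keep_missing_uncertainty)
    } else if (step == "duplicates") {
      records <- remove_duplicates(records, config$dup_precision)
    } else if (step == "coordinates") {
      flagged <- flag_coordinate_issues(records, layers, config)
      tab <- table(flagged$qc_flag)
      for (r in names(reasons)) {
        reasons[r] <- reasons[r] + if (r %in% names(tab)) tab[[r]] else 0L
      }
      records <- flagged[flagged$qc_flag == "none",
        setdiff(names(flagged), "qc_flag"), drop = FALSE]
    } else if (step == "outliers") {
      drop <- logical(nrow(records))
      for (sp in unique(records$species)) {
        i <- which(records$species == sp)
        drop[i] <- flag_spatial_outliers(records[i, , drop = FALSE],
          config$outlier_multiplier, config$min_records)
      }
      records <- records[!drop, , drop = FALSE]
    }
    removals[step] <- before - nrow(records)
  }

  per_species <- table(records$species)
  report <- structure(
    list(
      n_input = n_input,
      n_output = nrow(records),
      removals = removals,
      coordinate_reasons = reasons,
      n_missing_uncertainty = n_missing_unc,
      n_unknown_basis = n_unknown_basis,
      n_malformed_uncertainty = n_malformed_unc,
      per_species = as.list(per_species),
      steps = config$steps,
      config_hash = qc_config_hash(config)
    ),
    class = "qc_report"
  )
  structure(list(records = records, report = report), class = "qc_result")
}

# Stable digest of the config so the step order in force is logged.
qc_config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  # small rolling polynomial hash; stability matters, cryptography does not
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d -> %d records\n", x$n_input, x$n_output))
  for (s in names(x$removals)) {
    cat(sprintf("  %-12s removed %d\n", s, x$removals[[s]]))
  }
  cat("  coordinate reasons:",
    paste(sprintf("%s=%d", names(x$coordinate_reasons), x$coordinate_reasons),
      collapse = ", "), "\n")
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
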