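# Round half away from zero, the convention used for reported percentages.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Merge Red List labels with model predictions
#'
#' Every species of the universe appears exactly once. Species with a proper
#' Red List label (LC/NT/VU/EN/CR) keep it and are never overwritten by a
#' prediction; DD species count as unlabeled and receive a prediction when
#' one exists; species with neither are "not evaluated".
#'
#' @param rl_labels Data frame `species`, `category` (LC/NT/VU/EN/CR/DD).
#' @param predictions Data frame `species`, `category` and optionally
#'   `confidence` (predicted statuses, same category vocabulary).
#' @param species_universe Character vector of all species.
#' @return Data frame of class `assessment_table`: `species`, `status`,
#'   `source` (`rl_label`, `prediction`, `not_evaluated`), `confidence`.
#' @export
merge_assessments <- function(rl_labels, predictions, species_universe) {
  extra <- setdiff(predictions$species, species_universe)
  if (length(extra)) {
    stop("predicted species absent from universe: ",
      paste(head(extra, 5), collapse = ", "))
  }
  if (any(duplicated(species_universe))) stop("duplicated species in universe")
  status <- rep(NA_character_, length(species_universe))
  source <- rep("not_evaluated", length(species_universe))
  confidence <- rep(NA_real_, length(species_universe))

  pi <- match(species_universe, predictions$species)
  has_pred <- !is.na(pi)
  status[has_pred] <- predictions$category[pi[has_pred]]
  source[has_pred] <- "prediction"
  if ("confidence" %in% names(predictions)) {
    confidence[has_pred] <- predictions$confidence[pi[has_pred]]
  }

  proper <- rl_labels[rl_labels$category %in% RL_CLASSES, , drop = FALSE]
  li <- match(species_universe, proper$species)
  has_lab <- !is.na(li)
  status[has_lab] <- proper$category[li[has_lab]]
  source[has_lab] <- "rl_label"
  confidence[has_lab] <- NA_real_

  out <- data.frame(
    species = species_universe, status = status, source = source,
    confidence = confidence, stringsAsFactors = FALSE
  )
  class(out) <- c("assessment_table", class(out))
  out
}

# Map 5-class statuses to the binary grouping.
to_binary_status <- function(status) {
  ifelse(is.na(status), NA_character_,
    ifelse(status %in% THREATENED_CLASSES, "possibly_threatened",
      "not_threatened"))
}

#' Category count/percentage table
#'
#' Reproduces the shape of a merged assessment summary: per category, counts
#' and percentages for the Red List column (denominator: RL-labeled
#' species), the prediction column (denominator: predicted species) and the
#' merged column (denominator: all assessed species). Species neither
#' labeled nor predicted appear in an `NE/DD` row without a percentage.
#' Percentages are rounded to one decimal, half away from zero.
#'
#' @param assessment An `assessment_table` from [merge_assessments()].
#' @param scheme `"five_class"` or `"binary"`.
#' @return Data frame: `category`, `rl_count`, `rl_pct`, `pred_count`,
#'   `pred_pct`, `merged_count`, `merged_pct`.
#' @export
category_table <- function(assessment, scheme = c("five_class", "binary")) {
  scheme <- match.arg(scheme)
  cats <- if (scheme == "five_class") RL_CLASSES else
    c("not_threatened", "possibly_threatened")
  status <- if (scheme == "five_class") assessment$status else
    to_binary_status(assessment$status)
  rl <- assessment$source == "rl_label"
  pr <- assessment$source == "prediction"
  n_rl <- sum(rl)
  n_pr <- sum(pr)
  n_assessed <- n_rl + n_pr
  count_in <- function(mask) {
    vapply(cats, function(cc) sum(mask & !is.na(status) & status == cc), numeric(1))
  }
  rl_count <- count_in(rl)
  pred_count <- count_in(pr)
  merged_count <- rl_count + pred_count
  pct <- function(count, denom) {
    if (denom == 0) rep(NA_real_, length(count)) else
      round_half_up(100 * count / denom, 1)
  }
  out <- data.frame(
    category = c(cats, "NE/DD"),
    rl_count = c(rl_count, NA),
    rl_pct = c(pct(rl_count, n_rl), NA),
    pred_count = c(pred_count, NA),
    pred_pct = c(pct(pred_count, n_pr), NA),
    merged_count = c(merged_count, sum(assessment$source == "not_evaluated")),
    merged_pct = c(pct(merged_count, n_assessed), NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

# Shared per-group threat bookkeeping used by taxon and country summaries.
group_threat_counts <- function(assessment, group) {
  bin <- to_binary_status(assessment$status)
  src <- assessment$source
  g_levels <- sort(unique(group))
  group <- factor(group, levels = g_levels)
  tab <- data.frame(
    group = g_levels,
    n_species = as.integer(table(group)),
    n_threatened_rl = as.integer(tapply(
      !is.na(bin) & bin == "possibly_threatened" & src == "rl_label", group, sum)),
    n_threatened_pred = as.integer(tapply(
      !is.na(bin) & bin == "possibly_threatened" & src == "prediction", group, sum)),
    n_not_threatened_rl = as.integer(tapply(
      !is.na(bin) & bin == "not_threatened" & src == "rl_label", group, sum)),
    n_not_threatened_pred = as.integer(tapply(
      !is.na(bin) & bin == "not_threatened" & src == "prediction", group, sum)),
    n_not_evaluated = as.integer(tapply(src == "not_evaluated", group, sum)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$n_threatened <- tab$n_threatened_rl + tab$n_threatened_pred
  tab$n_assessed <- tab$n_species - tab$n_not_evaluated
  tab$frac_threatened <- ifelse(tab$n_assessed > 0,
    tab$n_threatened / tab$n_assessed, NA_real_)
  tab
}

#' Threat summary by taxonomic group
#'
#' Per-group counts of threatened / not-threatened species split by source
#' (Red List vs prediction) plus not-evaluated species, and two rankings:
#' groups with the most threatened species, and groups with the highest
#' threatened proportion among groups with more than `min_group_size`
#' assessed species. Fractions use assessed species as denominator. Ties are
#' broken by group name.
#'
#' @param assessment An `assessment_table`.
#' @param taxonomy Data frame `species`, `genus`, `family`, `order`.
#' @param level One of `"genus"`, `"family"`, `"order"`.
#' @param min_group_size Proportion ranking is restricted to groups with more
#'   than this many assessed species (default 10).
#' @return List of class `taxon_summary`: `table` (per-group counts),
#'   `top_by_count`, `top_by_proportion` (ranked group names).
#' @export
summarize_by_taxon <- function(assessment, taxonomy, level = "family",
                               min_group_size = 10) {
  stopifnot(level %in% c("genus", "family", "order"))
  grp <- taxonomy[[level]][match(assessment$species, taxonomy$species)]
  grp[is.na(grp)] <- "unknown"
  tab <- group_threat_counts(assessment, grp)
  by_count <- tab[order(-tab$n_threatened, tab$group), ]
  eligible <- tab[!is.na(tab$frac_threatened) & tab$n_assessed > min_group_size, ]
  by_prop <- eligible[order(-eligible$frac_threatened, eligible$group), ]
  structure(
    list(
      table = tab,
      top_by_count = by_count$group,
      top_by_proportion = by_prop$group
    ),
    class = "taxon_summary"
  )
}

#' Assign species to countries from cleaned occurrences
#'
#' A species occurs in a country iff at least one cleaned record falls in the
#' country's polygon; species can map to several countries. Records outside
#' all polygons are ignored for the assignment and counted.
#'
#' @param occurrences Cleaned occurrence data frame.
#' @param countries A `polygon_layer`.
#' @return Data frame `species`, `country` (one row per pair), with attribute
#'   `n_unassigned` (records in no polygon).
#' @export
assign_countries <- function(occurrences, countries) {
  loc <- locate_in_polygons(countries, occurrences$decimalLongitude,
    occurrences$decimalLatitude)
  ok <- !is.na(loc)
  pairs <- unique(data.frame(
    species = occurrences$species[ok],
    country = countries$name[loc[ok]],
    stringsAsFactors = FALSE
  ))
  pairs <- pairs[order(pairs$species, pairs$country), ]
  rownames(pairs) <- NULL
  attr(pairs, "n_unassigned") <- sum(!ok)
  pairs
}

#' Assign species to biomes from cleaned occurrences
#'
#' Same record-presence rule as [assign_countries()]: a species counts in
#' every biome where it has at least one record.
#'
#' @param occurrences Cleaned occurrence data frame.
#' @param biomes A `polygon_layer`.
#' @return Data frame `species`, `biome`.
#' @export
assign_biomes <- function(occurrences, biomes) {
  out <- assign_countries(occurrences, biomes)
  names(out)[names(out) == "country"] <- "biome"
  out
}

#' Per-country threat summary
#'
#' Counts of threatened species per country and the threatened fraction among
#' assessed species; the fraction is suppressed (`NA`) for countries with
#' fewer than `min_assessed` assessed species. A species occurring in several
#' countries counts once in each.
#'
#' @param assessment An `assessment_table`.
#' @param species_countries Data frame `species`, `country` from
#'   [assign_countries()].
#' @param min_assessed Minimum assessed species for the fraction to be shown.
#' @return Data frame of per-country counts and fractions.
#' @export
country_threat_summary <- function(assessment, species_countries,
                                   min_assessed = 5) {
  idx <- match(species_countries$species, assessment$species)
  sub <- assessment[idx, , drop = FALSE]
  tab <- group_threat_counts(sub, species_countries$country)
  tab$frac_threatened[tab$n_assessed < min_assessed] <- NA_real_
  names(tab)[names(tab) == "group"] <- "country"
  tab
}

#' Cross-validation accuracy per country
#'
#' For each country: the fraction of correctly classified held-out species
#' among all labeled species occurring there. Countries with no labeled
#' species are absent from the result.
#'
#' @param cv_species Data frame `species`, `correct` (logical): pooled
#'   held-out cross-validation predictions.
#' @param species_countries Data frame `species`, `country`.
#' @return Data frame `country`, `n_species`, `accuracy`.
#' @export
per_country_accuracy <- function(cv_species, species_countries) {
  m <- merge(species_countries, cv_species, by = "species")
  if (!nrow(m)) {
    return(data.frame(country = character(0), n_species = integer(0),
      accuracy = numeric(0)))
  }
  agg <- aggregate(correct ~ country, data = m,
    FUN = function(v) c(n = length(v), acc = mean(v)))
  out <- data.frame(
    country = agg$country,
    n_species = as.integer(agg$correct[, "n"]),
    accuracy = as.numeric(agg$correct[, "acc"]),
    stringsAsFactors = FALSE
  )
  out[order(out$country), ]
}

# Assessed fraction per group plus distribution summary and the rank
# correlation between group size and assessed fraction.
assessed_fraction_by <- function(labeled, group) {
  g_levels <- sort(unique(group))
  gf <- factor(group, levels = g_levels)
  n <- as.integer(table(gf))
  n_lab <- as.integer(tapply(labeled, gf, sum))
  frac <- n_lab / n
  q <- quantile(frac, c(0.025, 0.5, 0.975), names = FALSE)
  rho <- if (length(n) > 2 && sd(n) > 0 && sd(frac) > 0) {
    suppressWarnings(cor(n, frac, method = "spearman"))
  } else {
    NA_real_
  }
  list(
    table = data.frame(group = g_levels, n_species = n, n_labeled = n_lab,
      assessed_fraction = frac, stringsAsFactors = FALSE),
    quantiles = c(lower95 = q[1], median = q[2], upper95 = q[3]),
    size_rank_correlation = rho
  )
}

#' Diagnostics for taxonomic and geographic assessment bias
#'
#' For each grouping (genus, family, order, country, biome): the per-group
#' fraction of species carrying a Red List label, the 95% range and median of
#' that distribution, and the Spearman rank correlation between group size
#' and assessed fraction. A systematic assessment bias shows up as a bimodal
#' fraction distribution or a strong size correlation.
#'
#' @param labels Data frame `species`, `category` (DD counts as labeled:
#'   it was evaluated, just data-deficient).
#' @param species_universe Character vector of all species.
#' @param taxonomy Data frame `species`, `genus`, `family`, `order`.
#' @param species_countries Optional data frame `species`, `country`.
#' @param species_biomes Optional data frame `species`, `biome`.
#' @return Named list of class `bias_diagnostics`, one entry per grouping,
#'   each with `table`, `quantiles`, `size_rank_correlation`.
#' @export
bias_diagnostics <- function(labels, species_universe, taxonomy,
                             species_countries = NULL, species_biomes = NULL) {
  labeled <- species_universe %in% labels$species
  out <- list()
  for (level in c("genus", "family", "order")) {
    grp <- taxonomy[[level]][match(species_universe, taxonomy$species)]
    grp[is.na(grp)] <- "unknown"
    out[[level]] <- assessed_fraction_by(labeled, grp)
  }
  spatial <- list(country = species_countries, biome = species_biomes)
  for (nm in names(spatial)) {
    map <- spatial[[nm]]
    if (is.null(map)) next
    lab_map <- map$species %in% labels$species
    out[[nm]] <- assessed_fraction_by(lab_map, map[[nm]])
  }
  structure(out, class = "bias_diagnostics")
}
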