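test_that("merge precedence: labels win, predictions fill, rest not evaluated", {
  at <- merge_assessments(
    rl_labels = data.frame(species = "A", category = "LC"),
    predictions = data.frame(species = "B", category = "EN"),
    species_universe = c("A", "B", "C")
  )
  expect_identical(at$status, c("LC", "EN", NA))
  expect_identical(at$source, c("rl_label", "prediction", "not_evaluated"))
  # a species with both label and prediction keeps the label
  at2 <- merge_assessments(
    rl_labels = data.frame(species = "A", category = "VU"),
    predictions = data.frame(species = "A", category = "LC"),
    species_universe = "A"
  )
  expect_identical(at2$status, "VU")
  expect_identical(at2$source, "rl_label")
  # DD labels do not block predictions
  at3 <- merge_assessments(
    rl_labels = data.frame(species = "A", category = "DD"),
    predictions = data.frame(species = "A", category = "CR"),
    species_universe = "A"
  )
  expect_identical(at3$status, "CR")
  expect_identical(at3$source, "prediction")
  expect_error(
    merge_assessments(
      rl_labels = data.frame(species = "A", category = "LC"),
      predictions = data.frame(species = "Z", category = "LC"),
      species_universe = "A"
    ),
    "absent from universe"
  )
})

test_that("five-class category table reproduces the published merged arithmetic", {
  u <- mk_universe(
    label_counts = c(LC = 16349, NT = 1953, VU = 4864, EN = 4836, CR = 2498),
    pred_counts = c(LC = 11670, NT = 4, VU = 3569, EN = 4248, CR = 2200),
    n_total = 58429
  )
  at <- merge_assessments(u$labels, u$predictions, u$species)
  tab <- category_table(at, "five_class")
  expect_identical(tab$merged_count,
    c(28019, 1957, 8433, 9084, 4698, 6238))
  expect_identical(tab$rl_count[1:5], c(16349, 1953, 4864, 4836, 2498))
  expect_equal(tab$rl_pct[1:5], c(53.6, 6.4, 15.9, 15.9, 8.2))
  expect_equal(tab$merged_pct[1:5], c(53.7, 3.7, 16.2, 17.4, 9.0))
  # totals: 52,191 assessed of 58,429
  expect_identical(sum(tab$merged_count[1:5]), 52191)
  expect_identical(sum(at$source != "not_evaluated"), 52191L)
})

test_that("binary category table reproduces the published merged arithmetic", {
  u <- mk_universe(
    label_counts = c(LC = 18302, VU = 12198),
    pred_counts = c(LC = 11000, VU = 10691),
    n_total = 58429
  )
  at <- merge_assessments(u$labels, u$predictions, u$species)
  tab <- category_table(at, "binary")
  expect_identical(tab$category, c("not_threatened", "possibly_threatened", "NE/DD"))
  expect_identical(tab$merged_count, c(29302, 22889, 6238))
  expect_equal(tab$rl_pct[1:2], c(60.0, 40.0))
  expect_equal(tab$pred_pct[1:2], c(50.7, 49.3))
  expect_equal(tab$merged_pct[1:2], c(56.1, 43.9))
})

test_that("category table degenerate cases", {
  at <- merge_assessments(
    data.frame(species = c("a", "b"), category = c("CR", "CR")),
    data.frame(species = character(0), category = character(0)),
    c("a", "b")
  )
  tab <- category_table(at, "five_class")
  expect_equal(tab$rl_pct[tab$category == "CR"], 100)
  expect_identical(tab$merged_count[1:5], tab$rl_count[1:5])
  expect_true(all(tab$pred_count[1:5] == 0))
})

test_that("taxon summaries count, rank and filter as specified", {
  tax <- data.frame(
    species = sprintf("s%02d", 1:20),
    genus = "g",
    family = c(rep("fam_big", 14), rep("fam_small", 3), rep("fam_mid", 3)),
    order = "o",
    stringsAsFactors = FALSE
  )
  labels <- data.frame(
    species = sprintf("s%02d", 1:20),
    category = c(rep("VU", 6), rep("LC", 8), rep("EN", 3), rep("LC", 3)),
    stringsAsFactors = FALSE
  )
  at <- merge_assessments(labels,
    data.frame(species = character(0), category = character(0)),
    tax$species)
  ts <- summarize_by_taxon(at, tax, "family")
  tab <- ts$table
  expect_identical(sum(tab$n_species), 20L)
  big <- tab[tab$group == "fam_big", ]
  expect_identical(big$n_threatened, 6L)
  expect_identical(big$n_assessed, 14L)
  # count ranking: fam_big (6) > fam_small (3) > fam_mid (0)
  expect_identical(ts$top_by_count[1:2], c("fam_big", "fam_small"))
  # proportion ranking excludes groups with <= 10 assessed species, so the
  # 100%-threatened 3-species family does not appear
  expect_false("fam_small" %in% ts$top_by_proportion)
  expect_identical(ts$top_by_proportion, "fam_big")
  expect_equal(tab$frac_threatened[tab$group == "fam_small"], 1.0)
})

test_that("adding not-evaluated species never changes a threatened fraction", {
  labels <- data.frame(species = c("a", "b", "c"),
    category = c("VU", "LC", "EN"))
  tax <- data.frame(species = c("a", "b", "c", "d", "e"), genus = "g",
    family = "f", order = "o")
  at_small <- merge_assessments(labels,
    data.frame(species = character(0), category = character(0)), c("a", "b", "c"))
  at_big <- merge_assessments(labels,
    data.frame(species = character(0), category = character(0)),
    c("a", "b", "c", "d", "e"))
  f_small <- summarize_by_taxon(at_small, tax, "family")$table$frac_threatened
  f_big <- summarize_by_taxon(at_big, tax, "family")$table$frac_threatened
  expect_equal(f_small, f_big)
})

test_that("country assignment matches the ray-casting oracle", {
  w <- make_test_world(n_countries = 4)
  s <- generate_species(25, world = w, seed = 51)
  gen <- generate_occurrences(s, w, contamination_config(seed = 52))
  occ <- gen$occurrences
  got <- assign_countries(occ, w$countries)
  oracle <- do.call(rbind, lapply(seq_along(w$countries$id), function(ci) {
    ring <- w$countries$rings[[ci]]
    inside <- oracle_point_in_ring(ring, occ$decimalLongitude, occ$decimalLatitude)
    if (!any(inside)) return(NULL)
    data.frame(species = unique(occ$species[inside]),
      country = w$countries$name[ci], stringsAsFactors = FALSE)
  }))
  oracle <- oracle[order(oracle$species, oracle$country), ]
  rownames(oracle) <- NULL
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("species straddling two countries count in both", {
  w <- make_test_world(n_countries = 4)
  # country strips are 10 degrees wide starting at -20
  occ <- data.frame(
    record_id = c("r1", "r2"), species = "sp",
    decimalLongitude = c(-15, -5), decimalLatitude = c(0, 0),
    coordinateUncertaintyInMeters = NA_real_, basisOfRecord = "HUMAN_OBSERVATION"
  )
  got <- assign_countries(occ, w$countries)
  expect_identical(nrow(got), 2L)
})

test_that("country threat summary suppresses fractions under the floor", {
  labels <- data.frame(species = sprintf("s%d", 1:8),
    category = c(rep("VU", 4), rep("LC", 4)))
  at <- merge_assessments(labels,
    data.frame(species = character(0), category = character(0)),
    sprintf("s%d", 1:8))
  map <- data.frame(
    species = c(sprintf("s%d", 1:6), "s7", "s8", "s1"),
    country = c(rep("big", 6), "small", "small", "small")
  )
  cs <- country_threat_summary(at, map, min_assessed = 5)
  big <- cs[cs$country == "big", ]
  expect_identical(big$n_assessed, 6L)
  expect_equal(big$frac_threatened, 4 / 6)
  small <- cs[cs$country == "small", ]
  expect_identical(small$n_assessed, 3L)
  expect_true(is.na(small$frac_threatened)) # count kept, fraction suppressed
  expect_identical(small$n_threatened, 1L)
})

test_that("per-country accuracy equals brute-force recomputation", {
  cvs <- data.frame(species = sprintf("s%d", 1:6),
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  map <- data.frame(
    species = c("s1", "s2", "s3", "s4", "s5", "s6", "s1"),
    country = c("x", "x", "x", "y", "y", "y", "y")
  )
  pca <- per_country_accuracy(cvs, map)
  expect_equal(pca$accuracy[pca$country == "x"], 2 / 3)
  expect_equal(pca$accuracy[pca$country == "y"], 2 / 4) # s1 counts in y too
  # random instances against a direct loop
  set.seed(53)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    cvs2 <- data.frame(species = sprintf("q%d", 1:n),
      correct = runif(n) < 0.7)
    map2 <- data.frame(
      species = sprintf("q%d", sample(n, n, replace = TRUE)),
      country = sample(c("a", "b", "c"), n, replace = TRUE)
    )
    map2 <- unique(map2)
    pca2 <- per_country_accuracy(cvs2, map2)
    for (cc in pca2$country) {
      sp <- map2$species[map2$country == cc]
      expect_equal(pca2$accuracy[pca2$country == cc],
        mean(cvs2$correct[cvs2$species %in% sp]))
    }
  }
})

test_that("fully labeled universes give degenerate bias diagnostics", {
  tax <- data.frame(species = sprintf("s%d", 1:30), genus = "g",
    family = rep(c("f1", "f2", "f3"), each = 10), order = "o")
  labels <- data.frame(species = tax$species, category = "LC")
  bd <- bias_diagnostics(labels, tax$species, tax)
  expect_true(all(bd$family$table$assessed_fraction == 1))
  expect_equal(unname(bd$family$quantiles["median"]), 1)
})

test_that("random labeling centers fractions at the labeling rate", {
  set.seed(54)
  n <- 600
  tax <- data.frame(
    species = sprintf("s%d", 1:n), genus = "g",
    family = sprintf("f%d", sample(1:20, n, replace = TRUE)), order = "o"
  )
  labels <- data.frame(species = tax$species[runif(n) < 0.5], category = "LC")
  bd <- bias_diagnostics(labels, tax$species, tax)
  expect_lt(abs(unname(bd$family$quantiles["median"]) - 0.5), 0.1)
  # no size signal in random labeling
  expect_lt(abs(bd$family$size_rank_correlation), 0.6)
})

test_that("labeling that thins with group size yields a negative rank correlation", {
  set.seed(55)
  sizes <- c(5, 10, 20, 40, 80, 160)
  rows <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    data.frame(species = sprintf("c%d_s%d", i, seq_len(sizes[i])),
      country = sprintf("c%d", i))
  }))
  p_lab <- 0.95 - 0.8 * (match(rows$country, sprintf("c%d", 1:6)) - 1) / 5
  labels <- data.frame(species = rows$species[runif(nrow(rows)) < p_lab],
    category = "LC")
  tax <- data.frame(species = rows$species, genus = "g", family = "f", order = "o")
  bd <- bias_diagnostics(labels, rows$species, tax, species_countries = rows)
  expect_lt(bd$country$size_rank_correlation, -0.5)
})

test_that("global conservation holds in every summary", {
  w <- make_test_world()
  run <- run_assessment(n_species = 120, seed = 61, n_replicates = 10)
  at <- run$assessment
  n_universe <- nrow(run$species)
  expect_identical(nrow(at), n_universe)
  expect_identical(
    sum(at$source == "rl_label") + sum(at$source == "prediction") +
      sum(at$source == "not_evaluated"),
    n_universe
  )
  ts <- summarize_by_taxon(at, run$taxonomy, "family")
  expect_identical(sum(ts$table$n_species), n_universe)
  expect_identical(
    sum(ts$table$n_threatened_rl + ts$table$n_threatened_pred +
      ts$table$n_not_threatened_rl + ts$table$n_not_threatened_pred +
      ts$table$n_not_evaluated),
    n_universe
  )
})
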