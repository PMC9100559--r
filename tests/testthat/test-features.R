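test_that("EOO is undefined for degenerate point sets", {
  expect_true(is.na(compute_eoo(c(1, 2), c(3, 4))))
  expect_true(is.na(compute_eoo(c(1, 2, 3), c(1, 2, 3)))) # collinear
  expect_true(is.na(compute_eoo(rep(5, 10), rep(5, 10)))) # one unique point
})

test_that("EOO of a ~111-km square matches the geodesic area oracle within 1%", {
  half <- 0.5
  lon <- c(-half, half, half, -half)
  lat <- c(-half, -half, half, half)
  eoo <- compute_eoo(lon, lat)
  oracle <- oracle_hull_area_km2(lon, lat)
  expect_lt(abs(eoo - oracle) / oracle, 0.01)
})

test_that("EOO matches the geodesic oracle within 1% on 100 random point sets", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    lat0 <- runif(1, -50, 50)
    lon0 <- runif(1, -150, 150)
    span <- runif(1, 0.5, 12)
    n <- sample(3:60, 1)
    lon <- lon0 + runif(n, -span, span)
    lat <- lat0 + runif(n, -span, span)
    eoo <- compute_eoo(lon, lat)
    if (is.na(eoo)) next
    oracle <- oracle_hull_area_km2(lon, lat)
    worst <- max(worst, abs(eoo - oracle) / oracle)
  }
  expect_lt(worst, 0.01)
})

test_that("hull monotonicity: EOO of a subset never exceeds the superset's", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    lon <- runif(n, -10, 10)
    lat <- runif(n, -10, 10)
    sub <- sample(n, max(3, floor(n / 2)))
    full <- compute_eoo(lon, lat)
    part <- compute_eoo(lon[sub], lat[sub])
    if (!is.na(part)) expect_lte(part, full + 1e-9)
  }
})

test_that("AOO counts occupied 2-km cells", {
  # 5 jittered points within metres of each other: one cell
  expect_equal(compute_aoo(10 + runif(5, 0, 1e-4), 4 + runif(5, 0, 1e-4)), 4)
  # two points ~1,000 km apart: two cells
  expect_equal(compute_aoo(c(0, 9), c(0, 0)), 8)
  # never more cells than unique points
  set.seed(1)
  lon <- runif(40, -5, 5)
  lat <- runif(40, -5, 5)
  expect_lte(compute_aoo(lon, lat) / 4, 40)
})

test_that("AOO equals the brute-force cell count on 50 random sets", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:80, 1)
    lon <- runif(1, -100, 100) + runif(n, -3, 3)
    lat <- runif(1, -45, 45) + runif(n, -3, 3)
    expect_equal(compute_aoo(lon, lat), oracle_aoo_km2(lon, lat))
  }
})

test_that("latitudinal range is max minus min", {
  expect_equal(compute_lat_range(5), 0)
  expect_equal(compute_lat_range(c(-10, 23)), 33)
  set.seed(2)
  for (i in 1:50) {
    lat <- runif(sample(1:30, 1), -60, 60)
    expect_equal(compute_lat_range(lat), max(lat) - min(lat))
  }
})

test_that("biome presence agrees with a ray-casting oracle", {
  w <- make_test_world(n_biomes = 4)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:25, 1)
    lon <- runif(n, -19, 19)
    lat <- runif(n, -19, 19)
    pres <- biome_presence(lon, lat, w$biomes)
    oracle <- vapply(w$biomes$rings, function(ring) {
      as.integer(any(oracle_point_in_ring(ring, lon, lat)))
    }, integer(1))
    expect_identical(as.integer(pres), oracle)
  }
})

test_that("biome presence one-hot and single-biome worlds", {
  w <- make_test_world(n_biomes = 4)
  # biome bands are latitudinal: all points in band 3 of 4 ([0, 10))
  pres <- biome_presence(c(-5, 3, 8), c(2, 5, 9), w$biomes)
  expect_identical(as.integer(pres), c(0L, 0L, 1L, 0L))
  w1 <- make_test_world(n_biomes = 1)
  expect_identical(as.integer(biome_presence(0, 0, w1$biomes)), 1L)
})

test_that("climate summaries match direct raster lookup", {
  w <- make_test_world()
  flat <- ascii_grid(matrix(7, 10, 10), -20, -20, 4)
  cs <- climate_summary(c(-5, 5), c(-5, 5), flat)
  expect_equal(cs$mean, 7)
  expect_equal(cs$sd, 0)
  two <- ascii_grid(matrix(c(1, 3), 1, 2), 0, 0, 1)
  cs2 <- climate_summary(c(0.5, 1.5), c(0.5, 0.5), two)
  expect_equal(cs2$mean, 2)
  expect_equal(cs2$sd, 1) # population sd
  set.seed(4)
  lon <- runif(50, -19, 19)
  lat <- runif(50, -19, 19)
  v <- oracle_grid_lookup(w$climate, lon, lat)
  cs3 <- climate_summary(lon, lat, w$climate)
  expect_equal(cs3$mean, mean(v))
  expect_equal(cs3$sd, sqrt(mean((v - mean(v))^2)))
})

test_that("footprint fractions bin sampled values into half-open intervals", {
  vals <- ascii_grid(matrix(c(0.5, 5, 15, 30), 1, 4), 0, 0, 1)
  lon <- c(0.5, 1.5, 2.5, 3.5)
  lat <- rep(0.5, 4)
  expect_equal(
    footprint_features(lon, lat, vals, c(0, 1, 10, 20, Inf)),
    rep(0.25, 4)
  )
  low <- ascii_grid(matrix(0.2, 2, 2), 0, 0, 1)
  expect_equal(
    footprint_features(c(0.5, 1.5), c(0.5, 1.5), low),
    c(1, 0, 0, 0)
  )
  # histogram oracle on random samples
  w <- make_test_world()
  set.seed(5)
  lon <- runif(60, -19, 19)
  lat <- runif(60, -19, 19)
  v <- oracle_grid_lookup(w$footprint, lon, lat)
  edges <- c(0, 1, 10, 20, Inf)
  oracle <- vapply(1:4, function(k) mean(v >= edges[k] & v < edges[k + 1]),
    numeric(1))
  expect_equal(footprint_features(lon, lat, w$footprint, edges), oracle)
  expect_equal(sum(footprint_features(lon, lat, w$footprint, edges)), 1,
    tolerance = 1e-12)
})

test_that("species with degenerate hulls are dropped unless the fallback is on", {
  w <- make_test_world()
  occ <- data.frame(
    record_id = sprintf("r%d", 1:7),
    species = c(rep("few", 2), rep("many", 5)),
    decimalLongitude = c(1, 2, 4, 5, 6, 4.5, 5.5),
    decimalLatitude = c(1, 2, 4, 6, 4, 5.5, 4.2),
    coordinateUncertaintyInMeters = NA_real_,
    basisOfRecord = "HUMAN_OBSERVATION",
    stringsAsFactors = FALSE
  )
  fs <- assemble_features(occ, w, feature_config())
  expect_identical(fs$dropped$species, "few")
  expect_identical(fs$dropped$reason, "eoo_undefined")
  expect_identical(fs$features$species, "many")

  fs2 <- assemble_features(occ, w, feature_config(eoo_fallback = TRUE))
  expect_identical(nrow(fs2$dropped), 0L)
  few_row <- fs2$features[fs2$features$species == "few", ]
  expect_equal(few_row$eoo_km2, few_row$aoo_km2)
})

test_that("dropped count equals the species with fewer than 3 unique points", {
  w <- make_test_world()
  s <- generate_species(60, world = w, seed = 33)
  s$n_records <- pmax(1L, s$n_records %/% 8L) # force some tiny species
  gen <- generate_occurrences(s, w, contamination_config(seed = 34))
  fs <- assemble_features(gen$occurrences, w, feature_config())
  n_pts <- tapply(
    paste(gen$occurrences$decimalLongitude, gen$occurrences$decimalLatitude),
    gen$occurrences$species, function(v) length(unique(v))
  )
  # collinearity has probability 0 under continuous jitter, so < 3 unique
  # points is the only drop reason here
  expect_identical(sort(fs$dropped$species), sort(names(n_pts)[n_pts < 3]))
})

test_that("normalization is invertible and uses stored training statistics", {
  w <- make_test_world()
  s <- generate_species(40, world = w, seed = 35)
  gen <- generate_occurrences(s, w, contamination_config(seed = 36))
  fs <- assemble_features(gen$occurrences, w, feature_config())
  norm <- suppressWarnings(normalize_features(fs$features))
  # round trip
  back <- denormalize_features(norm$features, norm$params)
  for (col in setdiff(names(fs$features), "species")) {
    expect_equal(back[[col]], fs$features[[col]], tolerance = 1e-9)
  }
  # binary biome columns pass through untouched
  expect_identical(norm$features$biome_1, fs$features$biome_1)
  # log10(x+1) applied to counts: a species with 99 records maps to 2 pre-z
  p <- norm$params
  j <- which(p$columns == "occ_count")
  expect_equal(
    (log10(99 + 1) - p$mean[j]) / p$sd[j],
    (2 - p$mean[j]) / p$sd[j]
  )
  # applying stored params to new rows uses training statistics only
  half <- fs$features[1:10, ]
  norm_half <- normalize_features(half, params = norm$params)
  expect_equal(norm_half$features, norm$features[1:10, ], tolerance = 1e-12)
})

test_that("constant columns normalize to zeros with a warning", {
  df <- data.frame(species = c("a", "b"), occ_count = c(3, 3),
    clim_mean = c(1, 2))
  expect_warning(norm <- normalize_features(df), "zero-variance")
  expect_equal(norm$features$occ_count, c(0, 0))
})

test_that("computed EOO tracks the true range radius across species", {
  w <- make_test_world()
  s <- generate_species(200, world = w, seed = 37)
  gen <- generate_occurrences(s, w, contamination_config(seed = 38))
  fs <- assemble_features(gen$occurrences, w, feature_config())
  radius <- s$range_radius_km[match(fs$features$species, s$species)]
  rho <- cor(radius, fs$features$eoo_km2, method = "spearman")
  expect_gt(rho, 0.8)
})
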