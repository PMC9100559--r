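Package: treerisk
Title: Automated Extinction-Risk Assessment for Tree Species from Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for approximating IUCN Red List
    extinction-risk categories of tree species from georeferenced occurrence
    records. Provides occurrence-record quality control (basis-of-record,
    coordinate-uncertainty, duplicate, coordinate-issue and spatial-outlier
    filters), per-species feature extraction (extent of occurrence, area of
    occupancy, latitudinal range, biome presence, climate summaries, human
    footprint exposure), fully connected neural-network classifiers and
    regression models with stratified cross-validation, Monte-Carlo-dropout
    uncertainty quantification with accuracy-targeted confidence thresholds,
    and merged assessment tables with taxonomic and spatial summaries. A
    synthetic biodiversity-data generator produces toy reference layers and
    occurrence datasets with known class-dependent range structure so the
    whole pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
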