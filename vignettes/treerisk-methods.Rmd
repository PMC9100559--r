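---
title: "Assessing tree extinction risk from occurrence records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing tree extinction risk from occurrence records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treerisk)
```

## The problem

The IUCN Red List assigns species to the ordered threat categories LC < NT <
VU < EN < CR through an expert-driven process that is slow and incomplete:
tens of thousands of tree species have never been evaluated. Because Red
List criteria largely reflect range size, population size and decline,
quantities that can be proxied from georeferenced occurrence records, a
supervised model trained on the already-assessed species can approximate
the missing assessments at scale. `treerisk` implements that pipeline:

1. **Occurrence QC** — clean raw, aggregator-style occurrence tables;
2. **Features** — per-species range geometry, biome membership, climate and
   human-footprint exposure;
3. **Model** — fully connected networks (classifier and regression modes,
   5-class and binary label schemes) with stratified 5-fold cross-validation;
4. **Uncertainty** — Monte-Carlo dropout with an accuracy-targeted
   confidence threshold;
5. **Reporting** — merged label/prediction tables and taxonomic, country and
   biome summaries, plus assessment-bias diagnostics.

A synthetic data generator stands in for the real-world inputs (GBIF
occurrences, Red List labels, WWF biomes, footprint and climate rasters) so
that every stage runs, and is tested, without any download.

## The synthetic study system

`generate_world()` builds a toy world: a lon/lat extent with a sea margin,
latitudinal biome bands, longitudinal country strips, a smooth
human-footprint field (a few Gaussian pressure centers on a low wilderness
baseline), a linear latitude–temperature climate field, and a gazetteer of
capitals, country centroids and institutions with exclusion radii.
`generate_species()` then draws species whose spatial structure depends on a
latent true threat class — the core assumption that makes status learnable
from occurrences:

* range radius: log-normal with class medians 500 / 200 / 80 / 30 / 10 km
  (LC → CR) and shared `sdlog` 0.6;
* record count: log-normal with class medians 80 / 50 / 30 / 15 / 8 and
  `sdlog` 0.7, at least 1;
* footprint affinity: beta-distributed with mean rising 0.3 → 0.7 with
  threat severity; the affinity biases the range center toward
  high-footprint cells.

The medians produce overlapping but separable feature distributions, so a
classifier is clearly better than chance yet imperfect — the qualitative
regime of real Red List prediction. The default class mix (53.6 / 6.4 /
15.9 / 15.9 / 8.2 % for LC / NT / VU / EN / CR) copies the category
proportions of the labeled global tree flora, including the very thin NT
class. Occurrences are drawn on a local tangent plane (isotropic Gaussian,
sd = radius/2, truncated at the radius) and rejected onto land, so the
extent of occurrence approximates the range disc.

`generate_occurrences()` optionally contaminates records with the error
classes that plague aggregated occurrence data — the 0/0 point, latitude
equal to longitude, points at sea, points on capitals / centroids /
institutions, excessive coordinate uncertainty, exact duplicates,
far-displaced outliers, and disallowed basis-of-record values. Each record
receives at most one error; the per-record error type goes to a *sidecar*
table, never into the occurrence file, so the truth cannot leak into the
pipeline under test. Error rates in raw aggregator data are not well
characterized; the default 12% total load is a free choice, not a
calibration.

What the generator does **not** emulate: realistic biogeography (biomes are
bands, countries are strips), spatial sampling bias, taxonomic error,
temporal structure, or spatially autocorrelated label noise. Passing tests
on generator data therefore demonstrate the pipeline's *mechanics* — that
the features recover range structure and the model recovers a
class-dependent signal — not field performance on real GBIF data.

## Occurrence cleaning

`clean()` applies, in configurable order: basis-of-record filter (default:
human observation, preserved specimen, literature), coordinate-uncertainty
filter (strictly below 100 km), duplicate removal (one record per species ×
coordinates rounded to 6 decimals — sub-metre, so only true duplicates
collapse), coordinate tests (0/0 within 1e-5°, lat = lon, at-sea by the
land mask, gazetteer hits with radii 10 km / 1 km / 100 m for capitals /
centroids / institutions), and a spatial-outlier test.

Records with *missing* uncertainty are kept by default: aggregator records
commonly omit the field and dropping them would gut the dataset. A strict
mode (`keep_missing_uncertainty = FALSE`) is available.

The outlier rule flags records whose minimum great-circle distance to any
conspecific record exceeds Q3 + 5 × IQR of those minimum distances,
skipping species with fewer than 7 records, in a single pass (no iteration
to a fixed point). These constants follow the defaults of the widely used
coordinate-cleaning tools. Note one interaction worth knowing: on clustered
Gaussian ranges the rule flags a fraction of a percent of legitimate rim
points; that is inherent to any distance-quantile rule, and the QC report
makes the count visible. The report always reconciles — input minus the
per-step removals equals output — and logs a hash of the configuration,
because step order matters (e.g. several injected 0/0 records of one
species collapse as duplicates before the coordinate test sees them when
duplicates run first).

## Features

Per species, from cleaned records:

* `occ_count` — number of records;
* `eoo_km2` — extent of occurrence: area of the convex hull, computed in a
  cylindrical equal-area projection with the standard parallel and central
  meridian at the species' centroid (per species, so distortion stays
  small without zone lookup). Undefined for fewer than 3 unique or
  collinear points; such species are dropped (the default) or fall back to
  their AOO (`eoo_fallback = TRUE`).
* `aoo_km2` — area of occupancy: occupied 2 × 2 km cells × 4 km², on a grid
  in the same projection with a cell centered on the projection origin.
  AOO is anchor-sensitive by construction; the anchor is fixed and
  documented, and the test oracle uses the same anchor.
* `lat_range_deg` — latitudinal span;
* `biome_*` — presence bits (≥ 1 record in the biome polygon; boundary
  points go to the lowest biome id);
* `clim_mean`, `clim_sd` — nearest-cell climate samples (population sd);
* `footprint_1..4` — fractions of records in the footprint pressure bins
  [0, 1), [1, 10), [10, 20), [20, ∞), the four standard footprint
  categories.

Species with any undefined feature are omitted, mirroring the practice of
feeding the network complete feature sets only. Normalization applies
log10(x + 1) to the count/area columns and z-scores all non-binary columns
using **training-set statistics only**; the stored parameters are applied
unchanged to prediction-set rows, so no information flows back from the
species being predicted.

## Networks

The model is a fully connected network with hidden layers of 100, 60 and 20
rectified-linear units and dropout rate 0.1 on hidden activations — used
both as a regularizer and, at prediction time, as the uncertainty source.
Two output modes: a softmax classifier trained with cross-entropy, and a
regression head (one linear output) trained with squared error against the
ordinal class indices, decoded by rounding half-up and clipping. Argmax
ties break toward the less-threatened class, a conservative and
deterministic rule. Two label schemes: the five Red List classes, and the
binary grouping possibly threatened (VU + EN + CR) vs not threatened
(LC + NT), which is the scheme of choice under class imbalance.

Training uses Adam with batch size 256, at most 1000 epochs, and early
stopping when the validation loss has not improved for 50 epochs,
returning the best-validation-loss parameters. The learning rate is 0.01.
These two constants deserve a note: at the sample sizes used here (a few
hundred to ~1,000 labeled species) an "epoch" is only 1–4 minibatches, so
a 10-epoch patience would stop on transient plateaus and a 1e-3 learning
rate would need thousands of epochs; gradient-checked runs on separable
two-cluster data converge to near-zero validation MSE with the chosen
values and stall an order of magnitude higher with the smaller ones. Both
were fixed once, from those module-level convergence runs.

Cross-validation is stratified 5-fold (per-class fold sizes differ by at
most 1); in each fold the held-out fold doubles as the early-stopping
validation set, exactly the 80/20 usage described for the original
pipeline. This conflates model selection with evaluation slightly; an
inner split could be added, but the default keeps fidelity to the original
procedure. Reported accuracy pools the held-out predictions (equivalently,
a fold-size-weighted mean).

## Monte-Carlo dropout and the confidence threshold

`mc_predict()` runs 100 stochastic forward passes with dropout active. For
the classifier, confidence is the mean softmax probability of the argmax
class of the mean vector; for regression, replicates vote with their
rounded class and confidence is the modal fraction. Given a labeled
calibration set — the pooled held-out cross-validation predictions —
`find_threshold()` returns the smallest observed confidence t\* whose
retained set (confidence ≥ t\*, ties retained) reaches a target accuracy;
if the overall accuracy already meets the target, t\* is the minimum
confidence and nothing is left unclassified. The search is exact over the
candidate set by construction and is tested against exhaustive search.

Where the calibration split was ambiguous in the original description, the
package calibrates on the pooled held-out predictions and then applies t\*
to the unlabeled species — one threshold, estimated on data the per-fold
models never trained on.

## Merged assessments and summaries

`merge_assessments()` gives Red List labels absolute precedence: a species
with a proper label is never overwritten; DD species count as unlabeled and
receive predictions; species with neither are "not evaluated".
`category_table()` reports counts and percentages with per-column
denominators — labeled total, predicted total, assessed total — and rounds
half away from zero to one decimal; these conventions reproduce the
published merged-table arithmetic exactly, which is asserted in the test
suite. The five-class *prediction-column* percentages of the published
table do not match any of these denominators (their basis is unstated) and
are deliberately not reproduced.

Group summaries count a species in every country/biome where it has a
cleaned record, report threatened fractions over assessed species only
(suppressed below 5 assessed species for countries), rank families by
threatened count and — restricted to families with more than 10 assessed
species — by threatened proportion, and break ties by name. Bias
diagnostics report the per-group assessed fraction distribution (median and
95% range) and the Spearman correlation between group size and assessed
fraction, the two signatures a systematic assessment bias would leave.

## Numerical choices and degenerate inputs

* Distances are haversine on the mean Earth radius; areas use the exact
  equal-area property of the projection. The independent test oracle
  computes geodesic polygon areas (WGS84) on the densified hull boundary;
  agreement is within 1% on random point sets spanning up to ~25°.
* Records at exactly 0/0 are caught before the lat = lon test, which is
  caught before the sea and gazetteer tests; each record gets one flag.
* Zero-variance feature columns z-score to zero with a warning.
* Empty validation sets, dropout-free models passed to `mc_predict()`,
  unknown Red List categories, and predictions for species outside the
  universe are errors, not silent repairs.
* All stochastic stages are deterministic given their seed; the pipeline
  driver `run_assessment()` derives all stage seeds from one master seed.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at 2,200
simulated species (~1,100 labeled, ~145,000 raw records) — large enough
for stable cross-validation accuracies and class-dependent signal, small
enough to run on a laptop in about a minute. Oracle-agreement checks use
50–1,000 random instances per operation.

## Known limitations

* Toy geography only; no claim about accuracy on real occurrence data.
* The binary "possibly threatened" grouping inherits the Red List's
  category semantics; no attempt is made to model the underlying criteria
  (range decline, fragmentation, population counts).
* The regression mode treats categories as equidistant ordinals.
* MC-dropout confidence is a heuristic uncertainty measure; no calibration
  diagnostics (reliability curves, ECE) beyond the threshold procedure are
  provided.
* Name resolution / synonymy is out of scope; input occurrence tables are
  assumed to use resolved species names.

## A worked run

```{r, eval = FALSE}
run <- run_assessment(n_species = 500, seed = 1, scheme = "binary",
  mode = "classifier")
run$qc$report                     # cleaning cascade bookkeeping
run$cv                            # cross-validated accuracy
run$threshold                     # accuracy-targeted confidence threshold
category_table(run$assessment, "binary")
summarize_by_taxon(run$assessment, run$taxonomy, "family")$top_by_count
```
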