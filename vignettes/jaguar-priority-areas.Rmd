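---
title: "From occurrence records to priority areas: the jagconn methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From occurrence records to priority areas: the jagconn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jagconn)
```

## The problem

Jaguars (*Panthera onca*) persist in landscapes where habitat has been
fragmented by deforestation and land-use change. Planning for the species'
conservation at a national scale requires answering four linked questions:
where could the species occur, which remnants of natural cover inside that
range are large enough to matter, how are those remnants connected for a
disperser, and which of them deserve conservation versus recovery
attention. `jagconn` implements that chain as a tested, reproducible
pipeline operating on co-registered rasters (habitat suitability,
elevation, land cover, human footprint, protection, regions) and a table
of occurrence records, and ships a seeded synthetic-landscape generator so
every stage runs and is verifiable without any external geodata.

## Record quality control

Occurrence records compiled from heterogeneous sources differ widely in
trustworthiness. Each record is scored on three attributes:

* **evidence** — preserved specimens and machine observations (camera
  traps) are high; human observations and material samples medium; records
  with no stated evidence low;
* **source** — peer-reviewed articles and expert-validated records high;
  museums medium; aggregated biodiversity datasets are of mixed provenance
  and default to medium (configurable to high via
  `reliability_table(dataset_level = "high")`);
* **geographic precision** — department plus municipality high, department
  alone medium, municipality alone or neither low.

Credibility is the weaker of evidence and source; overall reliability the
weaker of credibility and precision (ordering low < medium < high). The
minimum rule is a deliberate design choice: the attribute tables give
per-attribute levels but no combination rule, and a record is only as
reliable as its weakest attribute. Low-reliability records and exact
coordinate duplicates (string-normalized equality; no fuzzy matching) are
dropped, order preserved.

Surviving records are spatially thinned to a minimum inter-point distance
of 1 km, reducing spatial autocorrelation before any downstream use. The
thinning is randomized-greedy: while any pair is closer than the minimum,
the record with most neighbours inside the radius is removed, ties broken
by a seeded RNG. The result is maximal (no removed record can be re-added)
and reproducible. Distances use the haversine formula with Earth radius
6371 km — a deliberate, dependency-free contract, cross-checked in the
tests against an independent geodesic implementation. Exhaustive
enumeration on small point sets shows the greedy retained count stays
within 2 of the true maximum.

## Distribution post-processing

The pipeline consumes an already-fitted continuous suitability surface;
niche-model fitting itself (feature classes, regularization, model
selection, spatial cross-validation) is the business of existing modeling
tools and out of scope here. What the package owns is the published
post-processing chain:

* `prune_correlated()` — a pre-modeling helper that greedily eliminates
  predictors until no retained pair has |Spearman rho| ≥ 0.8, dropping
  from each offending pair the column with the larger mean absolute
  correlation (ties broken lexicographically). Constant columns cannot be
  ranked and are treated as uncorrelated, with a warning.
* `mtp_threshold()` — the minimum training presence: the lowest predicted
  suitability at any presence cell. Binarizing at this value guarantees
  zero omission on the training presences (asserted as an invariant).
  Presences on nodata cells are skipped with a warning; this situation is
  not specified anywhere authoritative, and skipping keeps the threshold
  defined whenever at least one presence is usable.
* `binarize()` — cell ≥ threshold, nodata propagated; the 1-cell count is
  non-increasing in the threshold.
* `elevation_refine()` — zeroes cells outside 0–3200 m, the elevational
  band with reported jaguar presence.

Point-to-cell lookup follows the standard raster convention: rows
top-down, half-open cell intervals under the grid's affine transform.

## Habitat patches

Habitat is the intersection of habitat land covers (dense, open, gallery
and fragmented forest, secondary vegetation, natural grasslands, swamps,
coastal swamps — configurable codes) with the binary distribution.
Connected components of the mask become patches; 8-connectivity is the
default so patch topology matches the corridor grid's diagonal moves
(4-connectivity is available). Patch ids are assigned in decreasing area
order with a row-major top-left tie-break, making labeling deterministic
and permutation-invariant. Patches under 23.5 km² — below stepping-stone
size for a dispersing jaguar — are discarded; the threshold is inclusive
(a patch of exactly 23.5 km² is kept). Areas are cell count × cell area;
synthetic grids are equal-area by construction.

## Connectivity network

Movement resistance is a linear rescale of the human footprint index onto
[1, 100] (`res = 1 + 99 (hfi − min)/(max − min)`; a constant surface
degenerates to 1 everywhere), so the most human-dominated cell is 100×
costlier to cross than the most natural one. Nodata is impassable.

Corridors are least-cost paths on the 8-connected grid. A move between
two cells costs the mean of their resistances times the move length (1 or
√2 cell sides) — the de facto convention of least-cost GIS tooling. The
search is a multi-source Dijkstra: every cell of the origin patch starts
at distance zero, so the path exits wherever is globally optimal, and
terminates on first contact with the destination patch. Under uniform
resistance 1 the cost-weighted distance (CWD) therefore equals the path
length. The implementation is compiled (Rcpp) and is verified cell-exact
(1e-9) against an independent shortest-path oracle built on igraph.

Only patch pairs whose nearest boundary cells lie within 113 km — the
species' median dispersal distance — are considered (edge-to-edge, not
centroid; the cap is inclusive). One corridor, the least-cost one, is kept
per pair. Corridors whose path crosses a third patch are pruned by
default: the connectivity they represent is already carried by the two
shorter links, as in standard linkage mapping.

Patch importance is current-flow (random-walk) betweenness centrality with
edge conductance 1/CWD: a unit current is injected across every
source–target pair of a connected component, and a node's throughput is
half the sum of absolute currents on its incident edges, endpoints
excluded. Values are absolute (unnormalized); isolated patches score 0.
Because the magnitudes depend on the tool and data, only ordinal and
structural properties are meaningful, and those are what the tests assert
(cut-vertex dominance on paths, leaf symmetry on stars, exact agreement
with a dense Laplacian-pseudoinverse solve on small random graphs).

## Prioritization

Four criteria per patch: the percentage of cells with HFI strictly under
15 (near-natural), patch area, the percentage of the patch inside
protected areas, and centrality. The three continuous criteria are min-max
normalized to [0, 1] across the patch set (a constant criterion
normalizes to 0 — the degenerate rule, applied also to a single-patch
landscape). Area enters as an ordinal weight instead of a normalized
value: 1 for [23.5, 1200) km², 2 for [1200, 5000), 3 for ≥ 5000 km²,
reflecting home-range and minimum-viable-population thresholds. Interval
boundaries go to the higher score — the conservative choice for
conservation, and configurable.

The total is the sum of the three normalized criteria plus the area score,
giving a range of [1, 6]. This summed reading is the central interpretive
decision of the scoring scheme: it is the only construction under which
category thresholds up to "greater than 4" are attainable and coherent.
Categories partition the range exactly: total > 4 → JPCA I; 3 < total ≤ 4
→ JPCA II; 2 < total ≤ 3 → JPRA I; total ≤ 2 → JPRA II (conservation
above 3, recovery at or below). The partition is exhaustive and mutually
exclusive, raising any single criterion can never demote a patch, and
scores are invariant to patch input order — all property-tested.

## The synthetic generator

`generate_landscape()` emulates the statistical structure the analysis
assumes, not any real geography:

* **suitability** — Gaussian-smoothed seeded white noise rescaled to
  [0, 1]; `smoothness` (default 8 cells) is the blur radius. The simplest
  spatially autocorrelated field.
* **elevation** — 0–5800 m, built from the inverse of suitability plus an
  independent relief field, mimicking strong orographic variation where
  high ground is less suitable.
* **land cover** — an independent smoothed field thresholded at
  `habitat_fraction`, with the habitat side split into the eight habitat
  classes by quantile and the rest into two non-habitat classes; smooth
  fields give contiguous, land-cover-like patches.
* **HFI** — low where suitability is high, remapped rank-preservingly so
  that `hfi_refugia_fraction` of cells fall under 15; contiguous refugia
  arise from the smoothness of the underlying field.
* **protected areas** — seeded circles biased to low-footprint cells;
  **regions** — a five-site Voronoi partition.

Records are drawn cell-proportionally to suitability and jittered
uniformly within their cell, so coordinate collisions arise only from the
deliberate duplicate injection (default 10%). Defaults — 100 × 100 grid at
1 km cells, 535 raw records, habitat fraction 0.57, refugia fraction 0.32,
attribute frequencies under which roughly a quarter of records fail the
reliability/duplicate filter — mirror the scale and filtering behaviour of
the national study system the pipeline was designed around.

What the generator does *not* emulate: real class proportions or spatial
anisotropy, gazetteer-style precision errors, observation effort biases
(roads, rivers), or the actual geography of any country. Passing tests on
synthetic landscapes therefore demonstrate algorithmic correctness and
pipeline determinism, not that any particular real-world patch or corridor
would be recovered.

## Numerical choices and degenerate inputs

* Report percentages are rounded half-up at the printed precision
  (`area_accounting()`); a zero denominator yields null rather than NaN.
* Empty inputs degrade gracefully: no habitat classes → empty patch list,
  empty network, empty portfolio; an empty distribution warns and reports
  0% protection.
* Thinning, record sampling and protected-area placement are the only
  stochastic steps; all take explicit seeds and the whole pipeline is
  byte-identical across repeat runs at a fixed configuration.
* Patch labeling ties, predictor-pruning ties and greedy-thinning ties all
  have stated deterministic (or seeded) tie-breaks.
* Problem sizes used by the test-suite verification runs: oracle
  equivalence on grids up to 30 × 30 (50 seeded trials), thinning
  guarantees on up to 500 points (100 seeded sets) with exhaustive
  comparison up to 12 points, centrality oracles on graphs up to 8 nodes,
  and end-to-end runs on 60 × 60 to 100 × 100 landscapes — sizes at which
  the independent oracles are exact and fast while exercising every code
  path.

## Known limitations

* One corridor per patch pair: per-pair corridor multiplicity (parallel
  swaths between the same two patches) is out of scope, so corridor counts
  are per-pair-best, not tool-style multiplicities.
* Least-cost corridors are polylines, not width-resolved swaths; no
  all-cell current maps are produced.
* The local equirectangular km frame is adequate for landscape windows of
  a few hundred km; continental-extent grids would need a true equal-area
  projection upstream.
* Niche-model fitting, calibration-area construction and real land-cover /
  footprint / protection data processing happen outside the package; the
  pipeline's contract starts at a continuous suitability raster.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(spec = landscape_spec(seed = 42))
report <- run_pipeline(cfg)
report
```

See the README for the printed output of this exact run and the
interpretation of each line.
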