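---
title: "Methods and design of sdmtoolkit"
author: "sdmtoolkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of sdmtoolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmtoolkit)
```

sdmtoolkit implements the computational steps of a MaxEnt-centred species
distribution modelling (SDM) workflow — occurrence curation, background/bias
construction, spatially structured cross-validation and model selection, SDM
post-processing, endemism mapping and least-cost connectivity — without any
desktop GIS. This vignette records the science behind each step, the tunable
parameters and their defaults, the numerical conventions, and the design
choices that were genuinely open.

## The raster data model

Everything operates on `sdm_grid`: a numeric matrix on a square lattice with
a lower-left map origin, row 1 being the northernmost row (the on-disk layout
of ESRI ASCII grids, the format MaxEnt consumes, and the package's raster
interchange format). NoData is held as `NA` in memory; the sentinel (default
−9999) exists only at the I/O boundary. Both `xllcorner` and `xllcenter`
headers are accepted on read; centre origins are normalised with
`corner = center − cellsize/2`, and the writer always emits the corner
convention.

All coordinates are planar, projected map units. No geodesic mathematics
appears anywhere: distance-based operations (rarefaction, buffers, kernel
densities, Voronoi assignment, cost paths) assume the layers were projected
before entering the pipeline, as MaxEnt-oriented workflows do in practice.

Cell ownership is half-open, `[x0, x0 + cellsize) × [y0, y0 + cellsize)`: a
point on a shared vertical edge belongs to the eastern cell, on a shared
horizontal edge to the northern cell. The convention is arbitrary but fixed,
documented, and exercised by tests; real data land on edges only through
deliberate construction.

`upscale()` aggregates `factor × factor` blocks with mean, median, majority,
minority, min, max or sum, ignoring NoData within a block (an all-NoData
block stays NoData). When the factor does not divide the dimensions, the
trailing partial blocks are aggregated over the cells they do contain rather
than dropped — coarsening should not silently shrink the study region.
Majority and minority ties break to the smallest value, which makes batch
runs reproducible.

## Occurrence rarefaction

Spatial rarefaction thins each species' records so that no two retained
points lie within the filter distance *d* (Euclidean, map units). The
retained-subset rule is **greedy keep-first in input order**, optionally
after a seeded shuffle. Greedy thinning is the common practice for "spatial
filtering" of occurrence data, is deterministic, and guarantees a *maximal*
subset: no removed point could be re-added without violating *d*. It does
not guarantee the *maximum-cardinality* subset — a point centred in a ring of
mutually distant points can, if encountered first, block all of them — and
different input orders may retain different (occasionally differently sized)
maximal subsets. The tests therefore verify feasibility and maximality
against exhaustive subset enumeration rather than asserting a maximum.

The multi-distance variant stratifies the filter by a heterogeneity class
grid (at most five classes, e.g. fine filtering in climatically heterogeneous
terrain, coarse filtering in homogeneous terrain). A pair of points spanning
two classes must satisfy the **larger** of the two distances: the
conservative resolution, leaving fewer residual clusters. Class distances
are distances in map units; workflows that think of filters as areas should
take the square root before calling. Occurrences falling on NoData class
cells are warned about and assigned the largest supplied distance.

## Background and bias surfaces

MaxEnt contrasts presences against background points, and where those
background points come from is one of the strongest levers on model quality.
Four constructors share one contract — template geometry in, positive weights
on sampleable cells, NoData elsewhere, never over environmental NoData:

* `bias_buffered_mcp()` — convex hull of the occurrences dilated by
  `buffer`; weight 1. One point degenerates to a disk, two or collinear
  points to a capsule.
* `bias_distance()` — union of disks of `radius`; weight 1.
* `bias_gaussian_kde()` — Gaussian kernel sum rescaled to max 1. Cells below
  `floor` (default 1e−6 of the maximum) are excluded outright rather than
  carrying vanishing weights, because a bias file must be strictly positive
  wherever sampling is permitted.
* `bias_alpha_hull()` — the local adaptive convex hull: single-linkage
  clustering of occurrences at threshold `alpha`, then each cluster's hull
  dilated by `buffer`, unioned.

The alpha-hull realisation was an open design point: the behaviour is
specified by its two limits, not by a construction. Single-linkage clustering
plus per-cluster buffered hulls reproduces both limits *exactly* (cell-set
equality, asserted in tests): `alpha` at or above the maximum pairwise
distance yields the buffered MCP, and `alpha` below the minimum pairwise
distance yields the buffered-points surface. Between the limits it produces
disjoint buffered polygons around spatial clusters, which is the intended
intermediate behaviour. The nesting
`distance ⊆ alpha-hull ⊆ MCP` holds for any `alpha` at equal buffer.

## Spatial jackknifing and model selection

Spatially structured k-fold cross-validation ("spatial jackknifing") guards
against the inflated performance estimates that random train/test splits
produce when occurrence data are spatially autocorrelated.
`partition_occurrences()` forms `k ∈ {3, 4, 5}` groups, either by seeded
multi-restart k-means on the coordinates (`segregated`, 25 restarts — the
clustering rule itself was unspecified, and k-means is the natural reading of
"spatial clustering of occurrence points") or uniformly at random balanced to
within one record. `voronoi_regions()` dissolves the occurrence Voronoi
diagram by group so every landscape cell belongs to its nearest occurrence's
group; `make_folds()` then trains on k−1 groups and tests on the withheld
one, and background for a fold is drawn only from the training groups'
regions.

Evaluation uses two statistics:

* **OER** (omission error rate): the fraction of test presences scoring
  *strictly below* the threshold. Strict comparison was a choice; the
  natural default threshold is the minimum training-presence score, under
  which a training set never omits itself.
* **AUC**: the rank-based (Mann–Whitney) probability that a random presence
  outranks a random background point, ties counting one half.

Candidate models are the Cartesian product of regularization multipliers
(default 1, MaxEnt's default) with five canonical feature-class
combinations — L; L,Q; H; L,Q,H; L,Q,H,P,T — in that order, which doubles as
the complexity ranking (1 = simplest). The threshold feature T can be
disabled, in which case the fifth combination becomes L,Q,H,P. The
`auto_features()` mapping (all classes at ≥80 records, L/Q/H at 15–79, L/Q at
10–14, L below 10) is provided as an explicit emulation of the classic
sample-size rule, never applied silently: the tuning route deliberately does
not limit feature classes by sample size.

`select_best()` is lexicographic: lowest mean OER, then highest mean AUC,
then lowest complexity rank. Residual ties — possible only between identical
summary statistics — fall to the lowest multiplier and then enumeration
order, keeping selection a total order (permutation-invariant, tested).

`write_maxent_batch()` emits one `java` invocation per candidate × fold in
the MaxEnt 3.4 flag dialect (`betamultiplier`, per-feature toggles,
`biasfile`, `outputformat=cloglog|logistic|raw`); flag spellings live in a
single emitter table. The package never runs MaxEnt; for fully offline
pipelines `envelope_model()` supplies a deterministic percentile-envelope
scorer (suitability = fraction of layers whose cell value falls within the
per-layer `[p, 100−p]` presence envelope) so the entire jackknife cycle is
executable and testable end to end.

Post-processing: `binarize()` (fixed, minimum-training-presence, or
interpolated-percentile thresholds — percentiles interpolate linearly between
order statistics, R's type-7 rule), `split_by_clades()` (presence cells
assigned to the clade of the nearest occurrence; 2–10 clade groups;
outputs are disjoint and conserve the input presence cells), and
`enforce_dispersal()` (future suitability zeroed beyond `dmax` of any
currently occupied cell centre).

## Endemism and CANAPE

From a stack of binary range grids: richness is the cellwise presence count;
weighted endemism (WE) adds 1/(range size) for each species present, so the
landscape WE total equals the species count exactly (a test invariant);
corrected weighted endemism (CWE) is WE/richness — the mean range restriction
of the local assemblage, in (0, 1], NoData where richness is zero. Both
predicted-range (binary SDM) and occupancy-based stacks work, since a stack
is just named binary grids.

CANAPE consumes rank-p fields exported by Biodiverse randomisations (the
randomisation itself stays in Biodiverse): a cell is significant when the
phylogenetic-endemism rank on the original or the comparison tree reaches
0.95; significant cells with both ranks at 0.99 are *super*; otherwise the
relative-PE rank classifies *neo* (≤ 0.025, significantly short branches),
*paleo* (≥ 0.975, significantly long branches), or *mixed*. These thresholds
follow the established CANAPE protocol and are all configurable, as are the
column names (defaults follow Biodiverse export conventions).
`reclassify_significance()` generalises the same rank logic to any exported
field with one- or two-tailed α.

## Least-cost connectivity

Cost surfaces are strictly positive per-cell traversal costs with NoData
impassable. Movement is 8-connected; the edge weight between adjacent cells
is `steplength × (costₐ + cost_b)/2`, with `steplength = cellsize`
(cardinal) or `cellsize·√2` (diagonal) — the ubiquitous GIS convention. The
Dijkstra engine is authored in the package so that tie-breaking is
deterministic: among equal-cost routes it prefers fewer steps, then a fixed
neighbour order (N, NE, E, SE, S, SW, W, NW) at each relaxation. That local
preference decides the retained predecessor deterministically; it compares
last moves, not whole move sequences, which is sufficient for reproducible
outputs. Tests cross-check the engine against exhaustive path enumeration on
4×4 grids (branch-and-bound pruning only of provably worse prefixes, so the
oracle stays exact) and against an independent graph-library implementation
on larger grids.

`cost_distance()` gives the accumulated-cost surface from any source set;
`least_cost_path()` returns the cell-centre polyline with accumulated cost
and geographic length; `pairwise_matrices()` reports both the along-path
cost and the along-path **geographic length** between all site pairs (the
length of the optimal route, not the straight-line separation — the two
readings of "LCP distance" differ, and the along-path reading is the one
implemented and documented). `corridor()` is the classic sum of the two
accumulated-cost surfaces; its minimum equals the LCP cost, every optimal
path cell attains it, and `mode = "excess"` rebases that minimum to 0.
Unreachable pairs are explicit results (`reachable = FALSE`, NA entries),
never errors. Floating-point cost comparisons use a relative tolerance of
1e−9.

## Synthetic data, and what passing tests do not show

The generators produce, under a fixed seed, byte-identical: smooth coordinate
gradients and box-filter-smoothed noise layers (optionally NoData-bordered),
Gaussian occurrence clusters with optional per-cluster labels, walled cost
surfaces, and randomisation tables whose rank-p fields are jittered within
sub-ranges that make the planted CANAPE category recoverable exactly.

`make_biased_scenario()` fixes the study conditions for the headline
cross-validation comparison: a 40×40 two-gradient landscape and one species
sampled only around three environmentally distinct cluster centres (15
records each, cluster standard deviation 2 cells) — a stylised but realistic
portrait of roadside/museum sampling bias. Under those conditions the
spatial jackknife reports a much higher omission rate than random folds
(every replicate, in both the tests and the acceptance script), because
withheld clusters are environmentally novel to the envelope scorer.

These fixtures emulate spatial clustering and environmental gradients; they
do not emulate observation error, taxonomic noise, non-equilibrium ranges,
interactions among species, or realistic climate fields. Passing tests
demonstrate the algorithms' correctness and the directional behaviour of
spatial versus random validation on clustered data — not predictive skill on
any real species.

Problem sizes throughout the suite and the acceptance script (grids of
10×10–40×40, tens of occurrences, 20 replicates) were chosen as the smallest
sizes at which each property is non-trivial, keeping the full suite
comfortably fast to run anywhere.

## Known limitations

* Raster I/O is ESRI ASCII; GeoTIFF and other binary formats are out of
  scope, as are reprojection and geodesic distances.
* The Voronoi-region and bias-surface constructions are O(cells ×
  occurrences) dense computations — appropriate at landscape-modelling
  resolutions, not for continental rasters at fine grain.
* The envelope scorer is intentionally simple; it stands in for an external
  SDM engine in tests and demonstrations, and makes no claim to MaxEnt's
  statistical behaviour beyond sharing the evaluation interface.
* Clustered-order rarefaction retains a maximal, not maximum, subset (see
  above).
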