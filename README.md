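# sdmtoolkit

A GIS-free R toolkit for the computational core of species distribution
modelling (SDM) workflows, for ecologists, biogeographers and landscape
geneticists who want the standard MaxEnt-era pipeline — occurrence curation,
background/bias design, spatially structured validation, post-processing,
endemism mapping and least-cost connectivity — as scriptable, testable
functions instead of desktop-GIS toolboxes.

## What it computes

* **Raster utilities** on ESRI ASCII grids (the format MaxEnt consumes):
  read/write, statistical upscaling (mean/median/majority/minority/min/max/
  sum), extent snapping, NoData redefinition, extent/polygon clipping, and
  value extraction at points.
* **Spatial rarefaction** of occurrence records: per species, retain a
  maximal subset with all pairwise distances ≥ *d*; a multi-distance variant
  stratifies *d* by a heterogeneity class grid (up to five classes).
* **MaxEnt bias surfaces**: buffered minimum convex polygon, distance
  buffers, Gaussian kernel density, and the buffered local adaptive convex
  hull (single-linkage clusters at distance α, per-cluster buffered hulls).
* **Spatial jackknifing** (geographically structured k-fold CV): k-means or
  random groups (k = 3–5), Voronoi group regions, leave-one-group-out folds,
  omission error rate OER = P(test presence score < threshold) and
  rank-based AUC, candidate grids over regularization multipliers × the five
  canonical feature-class combinations (L; L,Q; H; L,Q,H; L,Q,H,P,T), and
  lexicographic selection: min OER → max AUC → min complexity. Emits MaxEnt
  3.4 batch command files; a built-in percentile-envelope scorer makes the
  whole cycle runnable offline.
* **Post-processing**: binarisation (fixed / minimum-training-presence /
  percentile thresholds), clade splitting of binary SDMs by occurrence
  Voronoi regions (2–10 clades), dispersal-limited future projections.
* **Biodiversity grids**: richness, weighted endemism
  (WE(c) = Σ<sub>sp∈c</sub> 1/range<sub>sp</sub>), corrected weighted
  endemism (CWE = WE/richness), CANAPE neo/paleo/mixed/super categorisation
  of Biodiverse randomisation exports, and generic significance
  reclassification.
* **Connectivity**: Dijkstra cost-distance surfaces, least-cost paths,
  pairwise along-path cost and length matrices, and corridors
  (cost-distance sum; corridor minimum = LCP cost).
* **Seeded fixtures** for all of the above: gradient/patchy landscapes,
  clustered occurrences, walled cost surfaces, randomisation tables with
  planted categories.

## Worked example

Clustered, spatially biased sampling is the norm in occurrence data. The
snippet thins such a dataset, builds spatial folds, and contrasts the
omission error under spatial versus random cross-validation:

```r
library(sdmtoolkit)

sc <- make_biased_scenario(seed = 42)     # 2-gradient landscape, 3 clusters
thin <- rarefy(sc$occ, d = 2, seed = 42)  # 45 records -> 19
part <- partition_occurrences(thin, 3, "segregated", seed = 1)
part
#> <spatial_partition> k = 3 (segregated); group sizes: 7, 7, 5

reg  <- voronoi_regions(part, thin, sc$env$grad_x)
bias <- bias_alpha_hull(thin, alpha = 12, buffer = 4, sc$env$grad_x)
ev_s <- jackknife_evaluate(thin, sc$env, part, bias = bias,
                           region_grid = reg, n_background = 500, seed = 1)
ev_r <- jackknife_evaluate(thin, sc$env,
                           partition_occurrences(thin, 3, "random", seed = 1),
                           bias = bias, n_background = 500, seed = 1)
round(ev_s$folds, 3)
#>   fold oer   auc
#> 1    1   1 0.157
#> 2    2   1 0.182
#> 3    3   1 0.221
sprintf("mean OER  spatial: %.3f   random: %.3f", ev_s$mean_oer, ev_r$mean_oer)
#> "mean OER  spatial: 1.000   random: 0.206"
```

Every withheld spatial group is environmentally novel to a model trained on
the other two clusters, so the spatial jackknife reports total omission
(OER 1.0) where random folds — whose test points sit inside the sampled
clusters — report 0.206: random splitting flatters a model that does not
transfer. The tuning grid itself:

```r
enumerate_candidates(tuning_spec(rms = c(1, 2), threshold_enabled = FALSE))
#>    rm combo features
#> 1   1     1        L
#> 2   1     2       LQ
#> 3   1     3        H
#> 4   1     4      LQH
#> 5   1     5     LQHP
#> 6   2     1        L
#> ...
#> 10  2     5     LQHP
```

with `threshold_enabled = FALSE` dropping the threshold feature from the
fifth combination, per current MaxEnt 3.4.1 practice.

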