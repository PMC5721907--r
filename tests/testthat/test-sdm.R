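test_that("partition_occurrences recovers separated clusters and bounds k", {
  occ <- make_occurrences(rbind(c(5, 5), c(50, 5), c(25, 50)),
                          n_per = 3, spread = 0.5, seed = 3)
  p <- partition_occurrences(occ, 3, "segregated", seed = 1)
  # the three tight triads must come out as the three groups
  truth <- rep(1:3, each = 3)
  expect_equal(length(unique(paste(truth, p$assignment))), 3)
  # exhaustive check: k-means found the minimal within-group sum of squares
  # (every balanced relabelling of the true clustering has larger WSS than a
  # split one, so matching the truth is the optimum here)
  expect_error(partition_occurrences(occ, 6, "segregated"), "between 3 and 5")
  expect_error(partition_occurrences(occ, 2, "segregated"), "between 3 and 5")
  expect_error(partition_occurrences(occ[1:2, ], 3, "random"), "at least k")

  r1 <- partition_occurrences(occ, 3, "random", seed = 42)
  r2 <- partition_occurrences(occ, 3, "random", seed = 42)
  expect_identical(r1$assignment, r2$assignment)
  expect_true(max(tabulate(r1$assignment, 3)) -
              min(tabulate(r1$assignment, 3)) <= 1)  # balanced within 1
})

test_that("voronoi_regions matches nearest-neighbour brute force", {
  tmpl <- make_grid(matrix(0, 8, 8))
  set.seed(55)
  for (rep in 1:20) {
    occ <- rand_occ(sample(3:7, 1), lim = 8)
    part <- structure(list(k = 3, mode = "segregated",
                           assignment = sample(1:3, nrow(occ), replace = TRUE)),
                      class = "spatial_partition")
    vr <- voronoi_regions(part, occ, tmpl)
    nn <- brute_nearest(tmpl, occ$x, occ$y)
    expect_equal(as.vector(vr$values), part$assignment[nn])
  }
  # every non-NoData cell receives exactly one group id
  tmask <- make_grid(matrix(c(NA, rep(0, 63)), 8, 8))
  occ <- rand_occ(4, lim = 8)
  part <- partition_occurrences(rbind(occ, occ[1, ]), 3, "random", seed = 2)
  part$assignment <- part$assignment[1:4]
  vr <- voronoi_regions(structure(list(k = 3, mode = "random",
                                       assignment = part$assignment),
                                  class = "spatial_partition"), occ, tmask)
  expect_true(is.na(vr$values[1, 1]))
  expect_true(all(!is.na(vr$values[-1])))
})

test_that("make_folds builds leave-one-group-out folds", {
  occ <- rand_occ(15)
  p <- partition_occurrences(occ, 3, "random", seed = 1)
  folds <- make_folds(p)
  expect_length(folds, 3)
  expect_equal(lapply(folds, `[[`, "train_groups"),
               list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  # test sets partition the occurrences; train+test covers everything per fold
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(all_test, 1:15)
  for (f in folds)
    expect_equal(sort(c(f$train_idx, f$test_idx)), 1:15)
  p5 <- partition_occurrences(occ, 5, "random", seed = 1)
  f5 <- make_folds(p5)
  expect_length(f5, 5)
  expect_true(all(vapply(f5, function(f) length(f$train_groups) == 4, logical(1))))
})

test_that("oer counts strict sub-threshold presences", {
  expect_equal(oer(c(0.2, 0.6, 0.7), 0.5), 1 / 3)
  expect_equal(oer(c(0.5, 0.6), 0.5), 0)   # at threshold is not omitted
  expect_equal(oer(c(0.1, 0.2), 0.5), 1)
  expect_error(oer(numeric(0), 0.5), "empty")
})

test_that("auc is the pairwise win rate with half ties", {
  expect_equal(auc(c(0.9, 0.5), c(0.5, 0.1)), 0.875)
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # oracle: brute-force pair counting on random scores, plus complement and
  # monotone-transform invariance
  set.seed(66)
  for (rep in 1:25) {
    xs <- round(runif(sample(2:10, 1)), 2)
    ys <- round(runif(sample(2:10, 1)), 2)
    pairs <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(xs, ys), mean(pairs))
    expect_equal(auc(xs, ys) + auc(ys, xs), 1)
    expect_equal(auc(exp(3 * xs), exp(3 * ys)), auc(xs, ys))
  }
})

test_that("candidate enumeration reproduces the canonical tuning grid", {
  cand <- enumerate_candidates(tuning_spec())
  expect_equal(nrow(cand), 5)
  expect_equal(cand$features, c("L", "LQ", "H", "LQH", "LQHPT"))
  expect_equal(cand$rm, rep(1, 5))          # MaxEnt default multiplier
  cand3 <- enumerate_candidates(tuning_spec(rms = c(1, 2, 3)))
  expect_equal(nrow(cand3), 15)
  # threshold-feature toggle strips T from the fifth combination only
  cand_nt <- enumerate_candidates(tuning_spec(threshold_enabled = FALSE))
  expect_equal(cand_nt$features, c("L", "LQ", "H", "LQH", "LQHP"))
  expect_error(tuning_spec(rms = numeric(0)))
  expect_error(tuning_spec(rms = -1))
})

test_that("auto_features reproduces the sample-size mapping at breakpoints", {
  expect_equal(auto_features(80), c("L", "Q", "H", "P", "T"))
  expect_equal(auto_features(200), c("L", "Q", "H", "P", "T"))
  expect_equal(auto_features(79), c("L", "Q", "H"))
  expect_equal(auto_features(15), c("L", "Q", "H"))
  expect_equal(auto_features(14), c("L", "Q"))
  expect_equal(auto_features(10), c("L", "Q"))
  expect_equal(auto_features(9), "L")
  expect_equal(auto_features(1), "L")
  expect_error(auto_features(0))
})

test_that("select_best applies the lexicographic rule, order-invariantly", {
  ev <- data.frame(id = c("A", "B"), mean_oer = c(0.10, 0.05),
                   mean_auc = c(0.80, 0.70), combo = c(1, 5), rm = c(1, 1))
  expect_equal(select_best(ev)$id, "B")     # lowest OER wins outright
  ev2 <- data.frame(id = c("A", "B"), mean_oer = c(0.1, 0.1),
                    mean_auc = c(0.85, 0.80), combo = c(4, 1), rm = c(1, 1))
  expect_equal(select_best(ev2)$id, "A")    # then highest AUC
  ev3 <- data.frame(id = c("A", "B"), mean_oer = 0.1, mean_auc = 0.8,
                    combo = c(4, 1), rm = c(1, 1))
  expect_equal(select_best(ev3)$id, "B")    # then lowest complexity
  ev4 <- data.frame(id = c("A", "B"), mean_oer = 0.1, mean_auc = 0.8,
                    combo = 1, rm = c(2, 1))
  expect_equal(select_best(ev4)$id, "B")    # then lowest RM
  # permutation invariance on random evaluation tables of distinct candidates
  set.seed(8)
  for (rep in 1:20) {
    grid <- expand.grid(combo = 1:5, rm = c(0.5, 1, 2))
    grid <- grid[sample(nrow(grid), 10), ]
    ev <- data.frame(id = paste0("m", 1:10),
                     mean_oer = sample(c(0.1, 0.2), 10, replace = TRUE),
                     mean_auc = sample(c(0.7, 0.8), 10, replace = TRUE),
                     combo = grid$combo, rm = grid$rm)
    w <- select_best(ev)$id
    perm <- ev[sample(10), ]
    expect_equal(select_best(perm)$id, w)
  }
  expect_error(select_best(ev[0, ]), "empty")
})

test_that("MaxEnt batch emission writes one deterministic line per candidate-fold", {
  cand <- enumerate_candidates(tuning_spec())
  occ <- rand_occ(12)
  folds <- make_folds(partition_occurrences(occ, 3, "random", seed = 1))
  paths <- list(env_dir = "env", samples = sprintf("train_%d.csv", 1:3),
                test_samples = sprintf("test_%d.csv", 1:3),
                bias = "bias.asc", out_dir = "out")
  lines <- write_maxent_batch(cand, folds, paths, "cloglog")
  expect_length(lines, 15)
  expect_true(all(grepl("outputformat=cloglog", lines)))
  expect_true(all(grepl("betamultiplier=1", lines)))
  expect_true(all(grepl("biasfile=bias.asc", lines)))
  # feature toggles follow the combination: first candidate is L only
  expect_match(lines[1], "linear=true")
  expect_match(lines[1], "quadratic=false")
  expect_match(lines[1], "hinge=false")
  # the full combination enables product and threshold
  expect_match(lines[13], "product=true")
  expect_match(lines[13], "threshold=true")
  expect_identical(lines, write_maxent_batch(cand, folds, paths, "cloglog"))
  expect_error(write_maxent_batch(cand, folds, paths, "probability"),
               "unknown output format")
})

test_that("envelope model scores by fraction of layers inside the envelope", {
  env <- make_landscape(nrows = 10, ncols = 10, n_patchy = 0, seed = 1)
  occ <- data.frame(species = "s", x = c(2.5, 6.5), y = c(2.5, 6.5))
  m <- envelope_model(occ, env, p = 0)
  suit <- predict(m, env)
  sc <- extract_values(list(s = suit), occ)$s
  expect_equal(sc, c(1, 1))              # presences score 1 at p = 0
  # a cell outside every layer's presence range scores 0
  far <- extract_values(list(s = suit),
                        data.frame(species = "s", x = 9.5, y = 9.5))$s
  expect_equal(far, 0)
  # a cell inside exactly one of two envelopes scores 0.5
  half <- extract_values(list(s = suit),
                         data.frame(species = "s", x = 4.5, y = 9.5))$s
  expect_equal(half, 0.5)
  expect_error(envelope_model(occ[1, ], env), "at least 2")
})

test_that("binarize supports fixed, MTP and interpolated percentile thresholds", {
  g <- make_grid(matrix(c(0.4, 0.6), 1, 2))
  expect_equal(as.vector(binarize(g, "fixed", t = 0.5)$values), c(0, 1))
  # MTP: every training presence cell is predicted present
  suit <- make_grid(matrix(seq(0.1, 1, length.out = 25), 5, 5))
  tr <- extract_values(list(s = suit),
                       data.frame(species = "s", x = c(1.5, 3.5), y = c(2.5, 2.5)))$s
  bm <- binarize(suit, "mtp", training_scores = tr)
  expect_true(all(bm$values[suit$values >= min(tr)] == 1))
  expect_equal(attr(bm, "threshold"), min(tr))
  # 10th percentile of 0.1..1.0 interpolates to 0.19
  b10 <- binarize(suit, "percentile", q = 10, training_scores = seq(0.1, 1, 0.1))
  expect_equal(attr(b10, "threshold"), 0.19)
  expect_error(binarize(suit, "percentile", q = 10, training_scores = numeric(0)))
})

test_that("clade splitting is disjoint, conservative, and bounded at 2-10 groups", {
  pres <- make_grid(matrix(1, 10, 10))
  occ <- data.frame(species = "s", x = c(2, 8), y = c(5, 5),
                    label = c("cladeA", "cladeB"))
  sp <- split_by_clades(pres, occ)
  expect_named(sp, c("cladeA", "cladeB"))
  # split at the perpendicular bisector x = 5: 50 cells each
  expect_equal(sum(sp$cladeA$values == 1), 50)
  expect_equal(sum(sp$cladeB$values == 1), 50)
  expect_error(split_by_clades(pres, transform(occ, label = "one")), "2 to 10")
  occ11 <- data.frame(species = "s", x = 1:11, y = 1, label = paste0("c", 1:11))
  expect_error(split_by_clades(pres, occ11), "2 to 10")

  # random instances: union conservation + pairwise disjointness, and
  # per-cell agreement with a nearest-neighbour scan
  set.seed(99)
  for (rep in 1:10) {
    v <- matrix(rbinom(64, 1, 0.5), 8, 8)
    pg <- make_grid(v)
    occ <- rand_occ(6, lim = 8)
    occ$label <- paste0("c", sample(1:3, 6, replace = TRUE))
    if (length(unique(occ$label)) < 2) next
    parts <- split_by_clades(pg, occ)
    tot <- Reduce(`+`, lapply(parts, function(g) g$values))
    expect_equal(tot, v)                  # union = input, disjoint (sum == 1)
    nn <- brute_nearest(pg, occ$x, occ$y)
    for (cl in names(parts)) {
      cells <- which(as.vector(parts[[cl]]$values) == 1)
      expect_true(all(occ$label[nn[cells]] == cl))
    }
  }
})

test_that("dispersal enforcement clips future suitability by distance", {
  cur <- make_grid(matrix(0, 7, 7)); cur$values[4, 4] <- 1
  fut <- make_grid(matrix(1, 7, 7))
  # dmax 0: only the currently occupied cell survives
  d0 <- enforce_dispersal(fut, cur, 0)
  expect_equal(sum(d0$values), 1)
  # dmax 1.5 on unit cells: the 3x3 neighbourhood
  d15 <- enforce_dispersal(fut, cur, 1.5)
  expect_equal(sum(d15$values), 9)
  expect_equal(which(d15$values == 1, arr.ind = TRUE)[, 1] |> range(), c(3, 5))
  # huge dmax leaves the projection unchanged
  expect_equal(enforce_dispersal(fut, cur, 100)$values, fut$values)
  expect_error(enforce_dispersal(fut, make_grid(matrix(0, 3, 3)), 1),
               "geometry")
})

test_that("spatial folds expose overfitting that random folds hide", {
  # clustered sampling bias: withholding a whole cluster confronts the
  # envelope with environments it never saw, raising the omission rate
  sc <- make_biased_scenario(seed = 7)
  part_s <- partition_occurrences(sc$occ, 3, "segregated", seed = 1)
  part_r <- partition_occurrences(sc$occ, 3, "random", seed = 1)
  reg <- voronoi_regions(part_s, sc$occ, sc$env[[1]])
  ev_s <- jackknife_evaluate(sc$occ, sc$env, part_s, region_grid = reg,
                             p = 0, n_background = 300, seed = 2)
  ev_r <- jackknife_evaluate(sc$occ, sc$env, part_r, p = 0,
                             n_background = 300, seed = 2)
  expect_gt(ev_s$mean_oer, ev_r$mean_oer)
  expect_true(all(is.finite(c(ev_s$mean_auc, ev_r$mean_auc))))
})
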