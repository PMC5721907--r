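# Spatially jackknifed SDM tuning: partitioning, folds, OER/AUC evaluation,
# candidate enumeration and selection, MaxEnt batch emission, and binary-SDM
# post-processing.

#' Partition occurrences into spatial groups
#'
#' Assigns each occurrence to one of `k` (3 to 5) groups. `"segregated"`
#' clusters the coordinates with seeded multi-restart k-means (geographically
#' coherent groups); `"random"` assigns groups uniformly at random, balanced
#' to within one record.
#'
#' @param occ occurrence data.frame.
#' @param k number of groups, between 3 and 5.
#' @param mode `"segregated"` or `"random"`.
#' @param seed integer seed (both modes are deterministic given it).
#' @return An object of class `spatial_partition`: list with `k`, `mode`, and
#'   integer `assignment` (one group id in `1:k` per occurrence).
#' @export
partition_occurrences <- function(occ, k, mode = c("segregated", "random"),
                                  seed = 1L) {
  occ <- as_occurrences(occ)
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 5L)
    stop("'k' must be between 3 and 5 spatial groups")
  n <- nrow(occ)
  if (n < k) stop("need at least k occurrences to form k groups")
  set.seed(seed)
  assignment <- if (mode == "segregated") {
    km <- stats::kmeans(cbind(occ$x, occ$y), centers = k, nstart = 25,
                        iter.max = 100)
    as.integer(km$cluster)
  } else {
    as.integer(sample(rep_len(seq_len(k), n)))
  }
  structure(list(k = k, mode = mode, assignment = assignment),
            class = "spatial_partition")
}

#' @export
print.spatial_partition <- function(x, ...) {
  cat(sprintf("<spatial_partition> k = %d (%s); group sizes: %s\n",
              x$k, x$mode, paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Voronoi group regions over a template grid
#'
#' Every non-NoData template cell takes the group of its nearest occurrence
#' (Thiessen polygons dissolved by group; ties go to the earliest record).
#'
#' @param partition a `spatial_partition`.
#' @param occ the occurrence data.frame the partition was built from.
#' @param template an `sdm_grid` supplying geometry and the data mask.
#' @return An `sdm_grid` of integer group ids.
#' @export
voronoi_regions <- function(partition, occ, template) {
  stopifnot(inherits(partition, "spatial_partition"), is_grid(template))
  occ <- as_occurrences(occ)
  if (nrow(occ) != length(partition$assignment))
    stop("partition and occurrence set sizes differ")
  ctr <- grid_centers(template)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  d2 <- outer(px, occ$x, function(a, b) (a - b)^2) +
        outer(py, occ$y, function(a, b) (a - b)^2)
  nearest <- max.col(-d2, ties.method = "first")
  out <- template
  v <- partition$assignment[nearest]
  v[is.na(as.vector(template$values))] <- NA_real_
  out$values <- matrix(v, nrow(template$values), ncol(template$values))
  out
}

#' Leave-one-group-out folds from a spatial partition
#'
#' Fold `i` trains on every group except `i` and tests on group `i`.
#'
#' @param partition a `spatial_partition`.
#' @return A list of `k` folds, each a list with `test_group`, `train_groups`,
#'   `train_idx`, `test_idx`.
#' @export
make_folds <- function(partition) {
  stopifnot(inherits(partition, "spatial_partition"))
  lapply(seq_len(partition$k), function(i) {
    list(test_group = i,
         train_groups = setdiff(seq_len(partition$k), i),
         train_idx = which(partition$assignment != i),
         test_idx = which(partition$assignment == i))
  })
}

#' Omission error rate
#'
#' Proportion of test-presence suitability scores falling strictly below the
#' threshold, i.e. presences misclassified as unsuitable.
#'
#' @param test_scores numeric suitability scores of test presences.
#' @param threshold suitability threshold.
#' @return Proportion in \[0, 1\].
#' @export
oer <- function(test_scores, threshold) {
  if (length(test_scores) == 0) stop("empty test score set")
  mean(test_scores < threshold)
}

#' Rank-based AUC
#'
#' Mann-Whitney estimate of the probability that a random presence scores
#' above a random background point; ties count one half.
#'
#' @param presence_scores,background_scores non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# canonical feature-class combinations, in printed order (complexity rank 1-5)
.feature_combos <- function(threshold_enabled = TRUE) {
  combos <- list("L", c("L", "Q"), "H", c("L", "Q", "H"),
                 c("L", "Q", "H", "P", "T"))
  if (!threshold_enabled) combos[[5]] <- c("L", "Q", "H", "P")
  combos
}

#' Tuning specification for MaxEnt candidate models
#'
#' @param rms positive regularization multipliers (MaxEnt default is 1).
#' @param combos which of the five canonical feature-class combinations to
#'   include (integer ids 1-5: L; L,Q; H; L,Q,H; L,Q,H,P,T).
#' @param threshold_enabled logical; when `FALSE` (the MaxEnt 3.4.1
#'   recommendation) the fifth combination drops the threshold feature.
#' @return A `tuning_spec` list.
#' @export
tuning_spec <- function(rms = 1, combos = 1:5, threshold_enabled = TRUE) {
  if (length(rms) == 0 || any(rms <= 0)) stop("'rms' must be positive")
  if (!all(combos %in% 1:5)) stop("'combos' must be drawn from 1:5")
  structure(list(rms = as.numeric(rms), combos = as.integer(sort(unique(combos))),
                 threshold_enabled = isTRUE(threshold_enabled)),
            class = "tuning_spec")
}

#' Enumerate candidate models from a tuning specification
#'
#' Cartesian product of regularization multipliers with the selected
#' feature-class combinations, combinations in their printed order.
#'
#' @param spec a [tuning_spec()].
#' @return A data.frame with columns `rm`, `combo` (complexity rank 1-5) and
#'   `features` (e.g. `"LQH"`).
#' @export
enumerate_candidates <- function(spec = tuning_spec()) {
  stopifnot(inherits(spec, "tuning_spec"))
  combos <- .feature_combos(spec$threshold_enabled)
  out <- expand.grid(combo = spec$combos, rm = spec$rms,
                     KEEP.OUT.ATTRS = FALSE)[, c("rm", "combo")]
  out$features <- vapply(combos[out$combo], paste, "", collapse = "")
  rownames(out) <- NULL
  out
}

#' Sample-size dependent "auto features" mapping
#'
#' Reproduces the classic MaxEnt auto-features rule: all feature classes from
#' 80 records, L/Q/H for 15-79, L/Q for 10-14, L only below 10. Offered as an
#' optional emulation — tuning over the five combinations is the package's
#' default route, which does not limit features by sample size.
#'
#' @param n occurrence record count (`>= 1`).
#' @return Character vector of feature-class letters.
#' @export
auto_features <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be at least 1")
  if (n >= 80) c("L", "Q", "H", "P", "T")
  else if (n >= 15) c("L", "Q", "H")
  else if (n >= 10) c("L", "Q")
  else "L"
}

#' Select the best candidate model
#'
#' Lexicographic rule: lowest mean omission error rate; among ties, highest
#' mean AUC; then lowest feature-class complexity (the printed combination
#' order, L simplest); residual ties go to the lowest regularization
#' multiplier, then first in enumeration order.
#'
#' @param evaluations data.frame with columns `mean_oer`, `mean_auc`, `combo`,
#'   `rm` (one row per candidate).
#' @return The winning row.
#' @export
select_best <- function(evaluations) {
  ev <- as.data.frame(evaluations)
  if (nrow(ev) == 0) stop("empty evaluation list")
  need <- c("mean_oer", "mean_auc", "combo", "rm")
  if (!all(need %in% names(ev)))
    stop("evaluations need columns: ", paste(need, collapse = ", "))
  ord <- order(ev$mean_oer, -ev$mean_auc, ev$combo, ev$rm,
               seq_len(nrow(ev)))
  ev[ord[1], , drop = FALSE]
}

# single source of truth for MaxEnt 3.4 command-line flag spellings
.maxent_flags <- list(
  feature = c(L = "linear", Q = "quadratic", H = "hinge", P = "product",
              T = "threshold"),
  rm = "betamultiplier",
  out_format = "outputformat",
  formats = c(cloglog = "cloglog", logistic = "logistic", raw = "raw"))

#' Emit a MaxEnt batch command file
#'
#' One `java` invocation line per candidate x fold, carrying the
#' regularization multiplier, explicit feature-class toggles, bias file,
#' train/test sample files and the output-format flag. Purely textual: no
#' paths are checked against the filesystem.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param folds fold list from [make_folds()].
#' @param paths named list of file paths: `env_dir`, `samples` and
#'   `test_samples` (character vectors indexed by fold), `bias`, `out_dir`.
#' @param output_format `"cloglog"`, `"logistic"` or `"raw"`.
#' @param maxent_jar path written into the command lines.
#' @return Character vector of command lines (one per candidate x fold).
#' @export
write_maxent_batch <- function(candidates, folds, paths,
                               output_format = "cloglog",
                               maxent_jar = "maxent.jar") {
  if (!output_format %in% names(.maxent_flags$formats))
    stop("unknown output format: ", output_format)
  lines <- character(0)
  for (ci in seq_len(nrow(candidates))) {
    feats <- strsplit(candidates$features[ci], "")[[1]]
    toggles <- vapply(names(.maxent_flags$feature), function(f)
      sprintf("%s=%s", .maxent_flags$feature[[f]],
              tolower(f %in% feats)), "")
    for (fi in seq_along(folds)) {
      samp <- if (length(paths$samples) >= fi) paths$samples[[fi]] else paths$samples[[1]]
      test <- if (length(paths$test_samples) >= fi) paths$test_samples[[fi]] else paths$test_samples[[1]]
      lines <- c(lines, paste(
        "java -mx1024m -jar", maxent_jar,
        sprintf("environmentallayers=%s", paths$env_dir),
        sprintf("samplesfile=%s", samp),
        sprintf("testsamplesfile=%s", test),
        if (!is.null(paths$bias)) sprintf("biasfile=%s", paths$bias),
        sprintf("outputdirectory=%s", paths$out_dir),
        sprintf("%s=%s", .maxent_flags$rm, format(candidates$rm[ci])),
        paste(toggles, collapse = " "),
        "autofeature=false",
        sprintf("%s=%s", .maxent_flags$out_format,
                .maxent_flags$formats[[output_format]]),
        "redoifexists autorun visible=false"))
    }
  }
  lines
}

#' Percentile-envelope suitability model
#'
#' A simple presence-only scorer used as the built-in stand-in for an external
#' SDM engine in fully offline pipelines: per environmental layer, the
#' presence values define a `[p, 100 - p]` percentile envelope, and a cell's
#' suitability is the fraction of layers whose value falls inside its
#' envelope.
#'
#' @param presences occurrence data.frame (training presences).
#' @param env named list of `sdm_grid` layers sharing geometry.
#' @param p envelope trim percentile in `[0, 50)`; `p = 0` uses the full
#'   presence range.
#' @return An object of class `envelope_model` with `predict()` support.
#' @export
envelope_model <- function(presences, env, p = 0) {
  presences <- as_occurrences(presences)
  if (nrow(presences) < 2) stop("need at least 2 presences")
  if (p < 0 || p >= 50) stop("'p' must be in [0, 50)")
  if (is_grid(env)) env <- list(layer1 = env)
  vals <- extract_values(env, presences)
  lims <- lapply(names(env), function(nm) {
    v <- vals[[nm]][vals$status == "ok"]
    if (!length(v)) stop("no presence falls on valid cells of layer ", nm)
    stats::quantile(v, c(p / 100, 1 - p / 100), names = FALSE, type = 7)
  })
  names(lims) <- names(env)
  structure(list(limits = lims, p = p), class = "envelope_model")
}

#' @rdname envelope_model
#' @param object a fitted `envelope_model`.
#' @param newdata named list of `sdm_grid` layers (same names as training).
#' @param ... unused.
#' @return `predict()` returns a suitability `sdm_grid` in \[0, 1\].
#' @export
predict.envelope_model <- function(object, newdata, ...) {
  if (is_grid(newdata)) newdata <- list(layer1 = newdata)
  nms <- names(object$limits)
  if (!all(nms %in% names(newdata)))
    stop("newdata lacks layer(s): ",
         paste(setdiff(nms, names(newdata)), collapse = ", "))
  tmpl <- newdata[[nms[1]]]
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  valid <- !is.na(tmpl$values)
  for (nm in nms) {
    g <- newdata[[nm]]
    stop_if_geometry_differs(tmpl, g)
    valid <- valid & !is.na(g$values)
    lim <- object$limits[[nm]]
    inside <- !is.na(g$values) & g$values >= lim[1] & g$values <= lim[2]
    acc <- acc + inside
  }
  out <- tmpl
  out$values <- ifelse(valid, acc / length(nms), NA_real_)
  out
}

#' Binarize a continuous suitability grid
#'
#' A cell becomes 1 when its score is at or above the threshold. The threshold
#' comes from a fixed value, the minimum training presence score (MTP), or a
#' percentile of the training presence scores (linear interpolation between
#' order statistics).
#'
#' @param suitability an `sdm_grid` of scores.
#' @param rule `"fixed"`, `"mtp"` or `"percentile"`.
#' @param t fixed threshold (rule `"fixed"`).
#' @param q percentile in \[0, 100\] (rule `"percentile"`).
#' @param training_scores presence scores (rules `"mtp"`/`"percentile"`).
#' @return A binary `sdm_grid` (values 0/1, NoData preserved), with the
#'   threshold attached as attribute `"threshold"`.
#' @export
binarize <- function(suitability, rule = c("fixed", "mtp", "percentile"),
                     t = NULL, q = NULL, training_scores = NULL) {
  stopifnot(is_grid(suitability))
  rule <- match.arg(rule)
  thr <- switch(rule,
    fixed = { if (is.null(t)) stop("rule 'fixed' needs 't'"); t },
    mtp = {
      if (!length(training_scores)) stop("rule 'mtp' needs training scores")
      min(training_scores)
    },
    percentile = {
      if (!length(training_scores)) stop("rule 'percentile' needs training scores")
      if (is.null(q) || q < 0 || q > 100) stop("'q' must be in [0, 100]")
      stats::quantile(training_scores, q / 100, names = FALSE, type = 7)
    })
  out <- suitability
  out$values <- ifelse(is.na(suitability$values), NA_real_,
                       as.numeric(suitability$values >= thr))
  attr(out, "threshold") <- thr
  out
}

#' Split a binary SDM by clade membership
#'
#' The landscape is divided into Voronoi polygons of the labelled occurrences;
#' each presence cell goes to the clade of its nearest occurrence. Outputs are
#' pairwise disjoint and their union reproduces the input presence cells.
#'
#' @param binary an `sdm_grid` with values 0/1.
#' @param occ occurrence data.frame with a `label` column holding 2 to 10
#'   distinct clade ids.
#' @return A named list of binary `sdm_grid`s, one per clade.
#' @export
split_by_clades <- function(binary, occ) {
  stopifnot(is_grid(binary))
  occ <- as_occurrences(occ)
  if (is.null(occ$label)) stop("occurrences need a 'label' (clade) column")
  clades <- sort(unique(occ$label))
  if (length(clades) < 2 || length(clades) > 10)
    stop("clade splitting supports 2 to 10 clade groups, got ", length(clades))
  ctr <- grid_centers(binary)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  d2 <- outer(px, occ$x, function(a, b) (a - b)^2) +
        outer(py, occ$y, function(a, b) (a - b)^2)
  nearest_clade <- occ$label[max.col(-d2, ties.method = "first")]
  pres <- !is.na(as.vector(binary$values)) & as.vector(binary$values) == 1
  out <- lapply(clades, function(cl) {
    g <- binary
    v <- as.vector(binary$values)
    v[pres & nearest_clade != cl] <- 0
    g$values <- matrix(v, nrow(binary$values), ncol(binary$values))
    g
  })
  names(out) <- clades
  out
}

#' Enforce dispersal limitation on a projected SDM
#'
#' Retains future suitability only within `dmax` (map units, centre to
#' centre) of some currently occupied cell; everything farther is set to 0 —
#' a species cannot track climate beyond its dispersal capacity.
#'
#' @param future an `sdm_grid` of projected suitability (binary or
#'   continuous).
#' @param current a binary `sdm_grid` of current presence.
#' @param dmax maximum dispersal distance in map units (`>= 0`).
#' @return The dispersal-limited future `sdm_grid`.
#' @export
enforce_dispersal <- function(future, current, dmax) {
  stopifnot(is_grid(future), is_grid(current), dmax >= 0)
  stop_if_geometry_differs(future, current)
  ctr <- grid_centers(current)
  src <- which(!is.na(current$values) & current$values == 1)
  out <- future
  if (!length(src)) {
    out$values[!is.na(out$values)] <- 0
    return(out)
  }
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  dmin <- rep(Inf, length(px))
  for (i in src)
    dmin <- pmin(dmin, sqrt((px - px[i])^2 + (py - py[i])^2))
  reach <- matrix(dmin <= dmax, nrow(future$values), ncol(future$values))
  out$values[!reach & !is.na(out$values)] <- 0
  out
}

#' Spatially jackknifed evaluation with the built-in envelope model
#'
#' Runs the full leave-one-spatial-group-out cycle: for each fold an envelope
#' model is trained on the training groups' presences, background points are
#' drawn from the bias surface restricted to the training groups' Voronoi
#' regions, and the withheld group supplies the test presences. Per fold it
#' reports the omission error rate (threshold = minimum training presence
#' score) and the rank AUC against the background sample.
#'
#' @param occ occurrence data.frame.
#' @param env named list of `sdm_grid` layers.
#' @param partition a `spatial_partition` of `occ` (spatial or random).
#' @param bias optional bias `sdm_grid`; defaults to uniform weight over the
#'   first layer's data cells.
#' @param region_grid optional group-id `sdm_grid` from [voronoi_regions()];
#'   when supplied, background sampling is restricted to training regions.
#' @param p envelope trim percentile.
#' @param n_background background points per fold.
#' @param seed integer seed for background draws.
#' @return A list with per-fold data.frame `folds` (`fold`, `oer`, `auc`) and
#'   scalars `mean_oer`, `mean_auc`.
#' @export
jackknife_evaluate <- function(occ, env, partition, bias = NULL,
                               region_grid = NULL, p = 0,
                               n_background = 1000, seed = 1L) {
  occ <- as_occurrences(occ)
  if (is_grid(env)) env <- list(layer1 = env)
  if (is.null(bias)) {
    bias <- env[[1]]
    bias$values <- ifelse(is.na(bias$values), NA_real_, 1)
  }
  folds <- make_folds(partition)
  res <- lapply(folds, function(f) {
    train <- occ[f$train_idx, , drop = FALSE]
    test <- occ[f$test_idx, , drop = FALSE]
    if (nrow(train) < 2 || nrow(test) < 1)
      return(data.frame(fold = f$test_group, oer = NA_real_, auc = NA_real_))
    m <- envelope_model(train, env, p = p)
    suit <- predict(m, env)
    tr_sc <- extract_values(suit, train)
    te_sc <- extract_values(suit, test)
    tr_ok <- tr_sc$value[tr_sc$status == "ok"]
    te_ok <- te_sc$value[te_sc$status == "ok"]
    if (!length(tr_ok) || !length(te_ok))
      return(data.frame(fold = f$test_group, oer = NA_real_, auc = NA_real_))
    bg <- sample_background(bias, n_background, seed = seed + f$test_group,
                            region_mask = region_grid,
                            groups = f$train_groups)
    bg$species <- "background"
    bg_sc <- extract_values(suit, bg)
    bg_ok <- bg_sc$value[bg_sc$status == "ok"]
    data.frame(fold = f$test_group,
               oer = oer(te_ok, threshold = min(tr_ok)),
               auc = if (length(bg_ok)) auc(te_ok, bg_ok) else NA_real_)
  })
  res <- do.call(rbind, res)
  list(folds = res,
       mean_oer = mean(res$oer, na.rm = TRUE),
       mean_auc = mean(res$auc, na.rm = TRUE))
}
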