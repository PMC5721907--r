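# Seeded synthetic-data generators. Every analysis in the package can be
# exercised offline from these: smooth/patchy environmental stacks, clustered
# occurrence point sets, cost surfaces with walls, and Biodiverse-style
# randomisation tables with planted significance categories.

# separable box-filter smoothing with edge renormalisation
.smooth2d <- function(m, k) {
  if (k <= 1) return(m)
  ker <- rep(1, k)
  sm_rows <- t(apply(m, 1, function(r) {
    num <- stats::filter(r, ker, sides = 2)
    den <- stats::filter(rep(1, length(r)), ker, sides = 2)
    as.numeric(num / den)
  }))
  out <- apply(sm_rows, 2, function(cl) {
    num <- stats::filter(cl, ker, sides = 2)
    den <- stats::filter(rep(1, length(cl)), ker, sides = 2)
    as.numeric(num / den)
  })
  matrix(out, nrow(m), ncol(m))
}

#' Generate a synthetic environmental landscape
#'
#' Produces a named stack of `sdm_grid` layers: `grad_x` increases strictly
#' west-to-east, `grad_y` strictly south-to-north, and `patchy*` layers are
#' smoothed seeded noise (spatially autocorrelated patches). An optional
#' NoData border emulates clipped study regions.
#'
#' @param nrows,ncols grid dimensions.
#' @param xll,yll,cellsize grid georeferencing (map units).
#' @param n_patchy number of patchy random layers.
#' @param smooth box-filter half width (cells) controlling patch size.
#' @param nodata_border width in cells of a NoData frame (0 = none).
#' @param seed integer seed; identical seeds give identical stacks.
#' @return Named list of `sdm_grid` layers.
#' @export
make_landscape <- function(nrows = 40, ncols = 40, xll = 0, yll = 0,
                           cellsize = 1, n_patchy = 1, smooth = 5,
                           nodata_border = 0, seed = 1L) {
  set.seed(seed)
  nr <- nrows; nc <- ncols
  xs <- xll + (seq_len(nc) - 0.5) * cellsize
  ys <- yll + (nr - seq_len(nr) + 0.5) * cellsize
  layers <- list(
    grad_x = matrix(xs, nr, nc, byrow = TRUE),
    grad_y = matrix(ys, nr, nc))
  for (i in seq_len(n_patchy))
    layers[[paste0("patchy", i)]] <- .smooth2d(matrix(stats::rnorm(nr * nc), nr, nc),
                                               smooth)
  if (nodata_border > 0) {
    b <- nodata_border
    for (nm in names(layers)) {
      layers[[nm]][c(seq_len(b), (nr - b + 1):nr), ] <- NA_real_
      layers[[nm]][, c(seq_len(b), (nc - b + 1):nc)] <- NA_real_
    }
  }
  lapply(layers, make_grid, xll = xll, yll = yll, cellsize = cellsize)
}

#' Generate clustered synthetic occurrences
#'
#' Gaussian clusters around the given centres, optionally labelled by
#' cluster (clade/haplotype emulation). With `spread = 0` all points sit on
#' their centres.
#'
#' @param centers two-column matrix of cluster centres (map units).
#' @param n_per points per cluster (recycled).
#' @param spread Gaussian standard deviation of each cluster (recycled).
#' @param species species id for all records.
#' @param labels optional character vector, one label per cluster.
#' @param seed integer seed.
#' @return Occurrence data.frame (`species`, `x`, `y`, and `label` when
#'   labelled).
#' @export
make_occurrences <- function(centers, n_per = 10, spread = 1,
                             species = "sp1", labels = NULL, seed = 1L) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  n_per <- rep_len(n_per, k); spread <- rep_len(spread, k)
  set.seed(seed)
  rows <- lapply(seq_len(k), function(i) {
    data.frame(species = species,
               x = centers[i, 1] + stats::rnorm(n_per[i], 0, spread[i]),
               y = centers[i, 2] + stats::rnorm(n_per[i], 0, spread[i]),
               cluster = i, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out$label <- rep(rep_len(labels, k)[out$cluster])
  out$cluster <- NULL
  as_occurrences(out)
}

#' Generate a synthetic cost surface with a high-cost wall
#'
#' Uniform base cost with a vertical wall of `wall_cost` through the middle
#' column; `gap_rows` punches passable gaps (rows keep base cost),
#' `wall_impassable` turns the wall into NoData instead.
#'
#' @param nrows,ncols,cellsize grid shape.
#' @param base_cost cost of ordinary cells.
#' @param wall_cost cost of wall cells.
#' @param gap_rows integer rows (top-down) left open in the wall.
#' @param wall_impassable logical; make the wall NoData.
#' @return A cost `sdm_grid`.
#' @export
make_cost_surface <- function(nrows = 9, ncols = 9, cellsize = 1,
                              base_cost = 1, wall_cost = 100,
                              gap_rows = integer(0),
                              wall_impassable = FALSE) {
  v <- matrix(base_cost, nrows, ncols)
  wc <- (ncols + 1) %/% 2
  v[, wc] <- if (wall_impassable) NA_real_ else wall_cost
  if (length(gap_rows)) v[gap_rows, wc] <- base_cost
  make_grid(v, cellsize = cellsize)
}

#' Generate a Biodiverse-style randomisation table with planted categories
#'
#' For every data cell of the template, rank-p fields (`P_PE_WE_P`,
#' `P_PHYLO_RPE_NULL2`, `P_PHYLO_RPE2`) are drawn (seeded, jittered within
#' safe sub-ranges) so that [canape_classify()] at default thresholds
#' recovers exactly the planted category. Categories are assigned from
#' `weights` cell by cell.
#'
#' @param template an `sdm_grid` supplying the cell lattice.
#' @param weights named numeric sampling weights over
#'   `non-significant`, `neo`, `paleo`, `mixed`, `super`.
#' @param seed integer seed.
#' @return A data.frame with `Axis_0`, `Axis_1` (cell centres), the three
#'   rank-p fields, and the `planted` category.
#' @export
make_randomization_table <- function(template,
                                     weights = c("non-significant" = 0.6,
                                                 neo = 0.1, paleo = 0.1,
                                                 mixed = 0.1, super = 0.1),
                                     seed = 1L) {
  stopifnot(is_grid(template))
  lv <- c("non-significant", "neo", "paleo", "mixed", "super")
  stopifnot(all(names(weights) %in% lv))
  ctr <- grid_centers(template)
  ok <- which(!is.na(template$values))
  set.seed(seed)
  planted <- sample(names(weights), length(ok), replace = TRUE,
                    prob = weights)
  n <- length(ok)
  runif_in <- function(lo, hi) stats::runif(n, lo, hi)
  # defaults: sig 0.95, super 0.99, rpe_low 0.025, rpe_high 0.975
  p_orig <- runif_in(0.2, 0.8)          # non-significant baseline
  p_comp <- runif_in(0.2, 0.8)
  p_rpe <- runif_in(0.2, 0.8)
  sig <- planted != "non-significant"
  p_orig[sig] <- stats::runif(sum(sig), 0.955, 0.985)   # significant, not super
  p_comp[sig] <- stats::runif(sum(sig), 0.2, 0.8)
  sup <- planted == "super"
  p_orig[sup] <- stats::runif(sum(sup), 0.992, 1)
  p_comp[sup] <- stats::runif(sum(sup), 0.992, 1)
  p_rpe[planted == "neo"] <- stats::runif(sum(planted == "neo"), 0, 0.02)
  p_rpe[planted == "paleo"] <- stats::runif(sum(planted == "paleo"), 0.98, 1)
  data.frame(Axis_0 = as.vector(ctr$X)[ok], Axis_1 = as.vector(ctr$Y)[ok],
             P_PE_WE_P = p_orig, P_PHYLO_RPE_NULL2 = p_comp,
             P_PHYLO_RPE2 = p_rpe, planted = planted,
             stringsAsFactors = FALSE)
}

#' Clustered-sampling-bias study scenario
#'
#' Builds the standard demonstration dataset for spatial versus random
#' cross-validation: a two-gradient landscape and one species sampled only
#' around three environmentally distinct cluster centres (strong spatial
#' sampling bias), so models trained on some clusters face genuinely novel
#' conditions in the withheld one.
#'
#' @param seed integer seed.
#' @param nrows,ncols landscape size in cells.
#' @param n_per occurrences per cluster.
#' @param spread cluster standard deviation in map units.
#' @return List with `env` (layer stack) and `occ` (occurrences).
#' @export
make_biased_scenario <- function(seed = 1L, nrows = 40, ncols = 40,
                                 n_per = 15, spread = 2) {
  env <- make_landscape(nrows = nrows, ncols = ncols, n_patchy = 0,
                        seed = seed)
  centers <- rbind(c(ncols * 0.2, nrows * 0.25),
                   c(ncols * 0.8, nrows * 0.3),
                   c(ncols * 0.5, nrows * 0.8))
  occ <- make_occurrences(centers, n_per = n_per, spread = spread,
                          seed = seed + 1L)
  occ$x <- pmin(pmax(occ$x, 0.01), ncols - 0.01)
  occ$y <- pmin(pmax(occ$y, 0.01), nrows - 0.01)
  list(env = env, occ = occ)
}
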