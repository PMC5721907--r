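# Bias surfaces for MaxEnt background selection.
#
# All constructors share the same contract: the returned grid has the
# template's geometry, weight values on the cells where background sampling is
# allowed, and NoData elsewhere. Regions are always intersected with the
# template's data cells, so weights are never emitted over environmental
# NoData.

# Euclidean distance from points (px, py) to segment (x1,y1)-(x2,y2)
.dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# distance from each (px, py) to the filled convex hull of xy (0 inside);
# handles 1-point (disk) and 2-point / collinear (segment) degenerate hulls
.dist_to_hull <- function(px, py, xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n == 1) return(sqrt((px - xy[1, 1])^2 + (py - xy[1, 2])^2))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[h, , drop = FALSE]
  if (nrow(hull) <= 2 || abs(pracma::polyarea(hull[, 1], hull[, 2])) < 1e-12) {
    # collinear: use the two most separated points as a segment
    dmat <- as.matrix(stats::dist(xy))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    return(.dist_to_segment(px, py, xy[ij[1], 1], xy[ij[1], 2],
                            xy[ij[2], 1], xy[ij[2], 2]))
  }
  inside <- pracma::inpolygon(px, py, hull[, 1], hull[, 2])
  d <- rep(Inf, length(px))
  m <- nrow(hull)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    d <- pmin(d, .dist_to_segment(px, py, hull[k, 1], hull[k, 2],
                                  hull[k2, 1], hull[k2, 2]))
  }
  d[inside] <- 0
  d
}

.bias_from_membership <- function(template, member, weights = 1) {
  out <- template
  v <- ifelse(member & !is.na(template$values), weights, NA_real_)
  out$values <- matrix(v, nrow(template$values), ncol(template$values))
  out
}

.occ_xy <- function(occ) {
  occ <- as_occurrences(occ)
  if (nrow(occ) == 0) stop("empty occurrence set")
  cbind(occ$x, occ$y)
}

#' Bias surface: buffered minimum convex polygon
#'
#' Background cells are the template cells whose centres fall inside the
#' convex hull of the occurrences dilated by `buffer` (weight 1). One point
#' gives a disk, two or collinear points a capsule.
#'
#' @param occ occurrence data.frame.
#' @param buffer dilation distance in map units (`>= 0`).
#' @param template an `sdm_grid` defining geometry and the valid-data mask.
#' @return An `sdm_grid` bias surface.
#' @export
bias_buffered_mcp <- function(occ, buffer, template) {
  stopifnot(is_grid(template), buffer >= 0)
  xy <- .occ_xy(occ)
  ctr <- grid_centers(template)
  d <- .dist_to_hull(as.vector(ctr$X), as.vector(ctr$Y), xy)
  .bias_from_membership(template, d <= buffer)
}

#' Bias surface: distance from observation points
#'
#' Background cells are the template cells whose centres lie within `radius`
#' of any occurrence — a union of disks (weight 1).
#'
#' @inheritParams bias_buffered_mcp
#' @param radius disk radius in map units (`>= 0`).
#' @return An `sdm_grid` bias surface.
#' @export
bias_distance <- function(occ, radius, template) {
  stopifnot(is_grid(template), radius >= 0)
  xy <- .occ_xy(occ)
  ctr <- grid_centers(template)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nrow(xy)))
    dmin <- pmin(dmin, sqrt((px - xy[i, 1])^2 + (py - xy[i, 2])^2))
  .bias_from_membership(template, dmin <= radius)
}

#' Bias surface: Gaussian kernel density of sampling localities
#'
#' Cell weight is the Gaussian kernel sum
#' \eqn{\sum_i \exp(-d_i^2 / (2h^2))} over occurrences, evaluated at cell
#' centres and rescaled to a maximum of 1. Cells whose rescaled weight falls
#' below `floor` are excluded (NoData) rather than carrying a near-zero
#' weight, since a MaxEnt bias file must be positive wherever sampling is
#' allowed.
#'
#' @inheritParams bias_buffered_mcp
#' @param h Gaussian bandwidth in map units (`> 0`).
#' @param floor exclusion threshold on the rescaled weight.
#' @return An `sdm_grid` bias surface with weights in (0, 1].
#' @export
bias_gaussian_kde <- function(occ, h, template, floor = 1e-6) {
  stopifnot(is_grid(template), h > 0)
  xy <- .occ_xy(occ)
  ctr <- grid_centers(template)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  w <- numeric(length(px))
  for (i in seq_len(nrow(xy)))
    w <- w + exp(-((px - xy[i, 1])^2 + (py - xy[i, 2])^2) / (2 * h * h))
  w <- w / max(w)
  .bias_from_membership(template, w >= floor, weights = w)
}

#' Bias surface: buffered local adaptive convex hull
#'
#' Occurrences are clustered by single-linkage at threshold `alpha`; each
#' cluster contributes the `buffer`-dilation of its convex hull (a disk for a
#' singleton, a capsule for two or collinear points), and the background
#' region is their union. With `alpha` at least the maximum pairwise distance
#' this equals the buffered minimum convex polygon; with `alpha` below the
#' minimum pairwise distance it equals the distance-from-points surface with
#' `radius = buffer`.
#'
#' @inheritParams bias_buffered_mcp
#' @param alpha point-aggregation distance in map units (`> 0`).
#' @param buffer hull dilation distance in map units (`>= 0`).
#' @return An `sdm_grid` bias surface.
#' @export
bias_alpha_hull <- function(occ, alpha, buffer, template) {
  stopifnot(is_grid(template), alpha > 0, buffer >= 0)
  xy <- .occ_xy(occ)
  cl <- if (nrow(xy) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"), h = alpha)
  ctr <- grid_centers(template)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  dmin <- rep(Inf, length(px))
  for (g in unique(cl))
    dmin <- pmin(dmin, .dist_to_hull(px, py, xy[cl == g, , drop = FALSE]))
  .bias_from_membership(template, dmin <= buffer)
}

#' Draw background points from a bias surface
#'
#' Samples cells with probability proportional to the bias weight (with
#' replacement) and returns their centre coordinates; used to build MaxEnt
#' background/SWD files and for fold evaluation.
#'
#' @param bias an `sdm_grid` bias surface (NoData = not sampleable).
#' @param n number of points.
#' @param seed integer seed.
#' @param region_mask optional logical matrix (or grid of group ids plus
#'   `groups`) restricting sampling to part of the landscape.
#' @param groups optional vector: when `region_mask` is a group-id grid, only
#'   cells in these groups are sampled.
#' @return A data.frame with columns `x`, `y`.
#' @export
sample_background <- function(bias, n, seed = 1L, region_mask = NULL,
                              groups = NULL) {
  stopifnot(is_grid(bias), n >= 1)
  w <- bias$values
  if (!is.null(region_mask)) {
    if (is_grid(region_mask)) {
      keep <- if (is.null(groups)) !is.na(region_mask$values)
              else !is.na(region_mask$values) & region_mask$values %in% groups
      w[!keep] <- NA_real_
    } else w[!region_mask] <- NA_real_
  }
  idx <- which(!is.na(w))
  if (!length(idx)) stop("no sampleable cells in the bias surface")
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n, replace = TRUE, prob = w[idx])]
  ctr <- grid_centers(bias)
  data.frame(x = as.vector(ctr$X)[pick], y = as.vector(ctr$Y)[pick])
}
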