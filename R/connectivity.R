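# Least-cost landscape connectivity on a friction raster.
#
# Moves are 8-connected; the edge weight between adjacent cells a and b is
# steplength * (cost_a + cost_b) / 2 with steplength = cellsize for cardinal
# and cellsize * sqrt(2) for diagonal moves (the ubiquitous GIS convention).
# NoData cells are impassable. Ties between equal-cost routes are broken
# deterministically: fewer steps first, then a fixed neighbour-order
# preference (N, NE, E, SE, S, SW, W, NW).

# neighbour offsets (drow, dcol) in tie-break preference order
.nbr_off <- cbind(drow = c(-1, -1, 0, 1, 1, 1, 0, -1),
                  dcol = c(0, 1, 1, 1, 0, -1, -1, -1))
.nbr_diag <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)

#' Validate a cost surface
#'
#' @param g an `sdm_grid` of per-cell traversal costs; all data values must be
#'   strictly positive, NoData is impassable.
#' @return The grid, invisibly.
#' @export
as_cost_surface <- function(g) {
  stopifnot(is_grid(g))
  v <- g$values[!is.na(g$values)]
  if (any(v <= 0)) stop("cost surface values must be strictly positive")
  invisible(g)
}

.snap_sources <- function(cost, pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  rc <- cell_of(cost, pts[, 1], pts[, 2])
  if (anyNA(rc$row)) stop("source point outside the grid extent")
  idx <- (rc$col - 1L) * nrow(cost$values) + rc$row
  if (any(is.na(cost$values[cbind(rc$row, rc$col)])))
    stop("source point on an impassable (NoData) cell")
  idx
}

# Multi-source Dijkstra over the cell lattice. Returns accumulated cost,
# hop count, predecessor cell and the move id used to enter each cell.
.dijkstra <- function(cost, src_idx, target_idx = NA_integer_) {
  as_cost_surface(cost)
  v <- cost$values
  nr <- nrow(v); nc <- ncol(v); n <- nr * nc
  cs <- cost$cellsize
  dist <- rep(Inf, n); steps <- rep(Inf, n)
  prev <- rep(NA_integer_, n); mv <- rep(NA_integer_, n)
  done <- is.na(as.vector(v))            # impassable cells never enter
  dist[src_idx] <- 0; steps[src_idx] <- 0
  reltol <- 1e-9
  repeat {
    d2 <- dist; d2[done] <- Inf
    u <- which.min(d2)
    if (!is.finite(d2[u])) break
    done[u] <- TRUE
    if (!is.na(target_idx) && u == target_idx) break
    ur <- ((u - 1L) %% nr) + 1L
    uc <- ((u - 1L) %/% nr) + 1L
    for (k in 1:8) {
      vr <- ur + .nbr_off[k, 1]; vc <- uc + .nbr_off[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      w <- (vc - 1L) * nr + vr
      if (done[w]) next
      cw <- v[vr, vc]
      if (is.na(cw)) next
      step <- if (.nbr_diag[k]) cs * sqrt(2) else cs
      nd <- dist[u] + step * (v[ur, uc] + cw) / 2
      tol <- reltol * max(1, abs(nd))
      if (nd < dist[w] - tol ||
          (abs(nd - dist[w]) <= tol &&
           (steps[u] + 1 < steps[w] ||
            (steps[u] + 1 == steps[w] && (is.na(mv[w]) || k < mv[w]))))) {
        dist[w] <- min(nd, dist[w])
        steps[w] <- steps[u] + 1
        prev[w] <- u; mv[w] <- k
      }
    }
  }
  list(dist = dist, steps = steps, prev = prev, nr = nr, nc = nc)
}

#' Accumulated-cost surface from source points
#'
#' Minimal accumulated traversal cost from any source to every cell;
#' unreachable cells (and impassable ones) are NoData.
#'
#' @param cost a positive cost `sdm_grid` (NoData = impassable).
#' @param sources two-column matrix or data.frame of source (x, y) points.
#' @return An `sdm_grid` of accumulated costs (0 at the sources).
#' @export
cost_distance <- function(cost, sources) {
  src <- unique(.snap_sources(cost, sources))
  res <- .dijkstra(cost, src)
  out <- cost
  d <- res$dist
  d[!is.finite(d)] <- NA_real_
  out$values <- matrix(d, res$nr, res$nc)
  out
}

.idx_to_xy <- function(g, idx) {
  nr <- nrow(g$values)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  cbind(x = g$xll + (c - 0.5) * g$cellsize,
        y = g$yll + (nr - r + 0.5) * g$cellsize)
}

#' Least-cost path between two points
#'
#' @param cost a positive cost `sdm_grid`.
#' @param a,b length-2 numeric (x, y) endpoints on passable cells.
#' @return An object of class `lcp_path`: list with `path` (matrix of cell
#'   centres from `a` to `b`), `cost` (accumulated cost), `length`
#'   (geographic along-path length in map units) and `reachable`. When no
#'   route exists, `reachable` is `FALSE` and `cost`/`length` are `NA`.
#' @export
least_cost_path <- function(cost, a, b) {
  ia <- .snap_sources(cost, rbind(a))
  ib <- .snap_sources(cost, rbind(b))
  if (ia == ib) {
    return(structure(list(path = .idx_to_xy(cost, ia), cost = 0,
                          length = 0, reachable = TRUE), class = "lcp_path"))
  }
  res <- .dijkstra(cost, ia, target_idx = ib)
  if (!is.finite(res$dist[ib]))
    return(structure(list(path = NULL, cost = NA_real_, length = NA_real_,
                          reachable = FALSE), class = "lcp_path"))
  idx <- ib
  chain <- idx
  while (!is.na(res$prev[idx])) {
    idx <- res$prev[idx]
    chain <- c(idx, chain)
  }
  xy <- .idx_to_xy(cost, chain)
  seglen <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  structure(list(path = xy, cost = res$dist[ib], length = sum(seglen),
                 reachable = TRUE), class = "lcp_path")
}

#' @export
print.lcp_path <- function(x, ...) {
  if (!x$reachable) cat("<lcp_path> unreachable\n")
  else cat(sprintf("<lcp_path> %d cells, accumulated cost %g, length %g\n",
                   nrow(x$path), x$cost, x$length))
  invisible(x)
}

#' Pairwise least-cost matrices among sites
#'
#' Runs one Dijkstra per site and returns two symmetric matrices with zero
#' diagonals: accumulated along-path cost, and geographic length of the
#' least-cost path. Unreachable pairs carry `NA`.
#'
#' @param cost a positive cost `sdm_grid`.
#' @param points two-column matrix/data.frame of at least two site
#'   coordinates; row names (or a `site` column) become dimnames.
#' @return A list with matrices `cost` and `length`.
#' @export
pairwise_matrices <- function(cost, points) {
  pts <- as.data.frame(points)
  default_rn <- identical(rownames(points), as.character(seq_len(nrow(pts))))
  labels <- if (!is.null(pts$site)) as.character(pts$site)
            else if (!is.null(rownames(points)) && !default_rn) rownames(points)
            else paste0("site", seq_len(nrow(pts)))
  xy <- as.matrix(pts[, intersect(c("x", "y"), names(pts))])
  if (ncol(xy) < 2) xy <- as.matrix(pts[, 1:2])
  n <- nrow(xy)
  if (n < 2) stop("need at least two sites")
  cm <- matrix(0, n, n, dimnames = list(labels, labels))
  lm <- cm
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- least_cost_path(cost, xy[i, ], xy[j, ])
      cm[i, j] <- cm[j, i] <- if (p$reachable) p$cost else NA_real_
      lm[i, j] <- lm[j, i] <- if (p$reachable) p$length else NA_real_
    }
  }
  list(cost = cm, length = lm)
}

#' Least-cost corridor between two points
#'
#' Cellwise sum of the accumulated-cost surfaces from the two endpoints. Its
#' minimum over the landscape equals the least-cost-path cost between them,
#' and every cell on an optimal path attains it. `mode = "excess"` subtracts
#' that minimum so the optimal corridor floor is 0.
#'
#' @param cost a positive cost `sdm_grid`.
#' @param a,b length-2 numeric (x, y) endpoints.
#' @param mode `"sum"` or `"excess"`.
#' @return An `sdm_grid` corridor surface.
#' @export
corridor <- function(cost, a, b, mode = c("sum", "excess")) {
  mode <- match.arg(mode)
  da <- cost_distance(cost, rbind(a))
  db <- cost_distance(cost, rbind(b))
  out <- da
  out$values <- da$values + db$values
  if (all(is.na(out$values))) stop("endpoints are mutually unreachable")
  if (mode == "excess")
    out$values <- out$values - min(out$values, na.rm = TRUE)
  out
}
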