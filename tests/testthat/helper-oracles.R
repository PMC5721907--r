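# Independent brute-force oracles used across the suite. These deliberately
# use naive enumeration, never the package's own algorithms.

# all-subsets check of a thinning result: feasibility (all pairwise distances
# >= per-point rule) and the maximum feasible cardinality, for n <= 12
brute_thinning <- function(xy, d) {
  n <- nrow(xy)
  stopifnot(n <= 12)
  dm <- as.matrix(dist(xy))
  feasible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(dm[idx, idx][upper.tri(diag(length(idx)))] >= d)
  }
  best <- 0
  maximal_sets <- list()
  for (code in 0:(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (!feasible(idx)) next
    # maximal iff no excluded point can be added
    rest <- setdiff(seq_len(n), idx)
    is_max <- all(vapply(rest, function(r) !feasible(c(idx, r)), logical(1)))
    if (is_max) maximal_sets[[length(maximal_sets) + 1]] <- idx
    best <- max(best, length(idx))
  }
  list(max_cardinality = best, maximal_sets = maximal_sets)
}

# exact minimal path cost by depth-first enumeration of simple paths with
# branch-and-bound pruning (prunes only provably worse prefixes)
brute_lcp_cost <- function(cost_grid, a_rc, b_rc) {
  v <- cost_grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- cost_grid$cellsize
  off <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
  dia <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, acc) {
    if (acc >= best) return()
    if (r == b_rc[1] && c == b_rc[2]) { best <<- acc; return() }
    visited[r, c] <<- TRUE
    for (k in 1:8) {
      r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visited[r2, c2] || is.na(v[r2, c2])) next
      step <- if (dia[k]) cs * sqrt(2) else cs
      dfs(r2, c2, acc + step * (v[r, c] + v[r2, c2]) / 2)
    }
    visited[r, c] <<- FALSE
  }
  if (is.na(v[a_rc[1], a_rc[2]]) || is.na(v[b_rc[1], b_rc[2]])) return(Inf)
  dfs(a_rc[1], a_rc[2], 0)
  best
}

# igraph-based accumulated cost surface (independent of the package Dijkstra)
igraph_cost_distance <- function(cost_grid, src_xy) {
  v <- cost_grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- cost_grid$cellsize
  id <- function(r, c) (c - 1) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  off <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
  dia <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    for (k in 1:8) {
      r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(v[r2, c2])) next
      step <- if (dia[k]) cs * sqrt(2) else cs
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
      w <- c(w, step * (v[r, c] + v[r2, c2]) / 2)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(igraph::set_edge_attr(g, "weight", value = w),
                        edge.attr.comb = "min")
  if (igraph::vcount(g) < nr * nc)
    g <- igraph::add_vertices(g, nr * nc - igraph::vcount(g))
  src <- sdmtoolkit::cell_of(cost_grid, src_xy[1], src_xy[2])
  d <- igraph::distances(g, v = id(src$row, src$col))
  out <- matrix(as.numeric(d), nr, nc)
  out[is.na(v)] <- NA
  out
}

# nearest labelled point for every cell centre, by full scan
brute_nearest <- function(template, xs, ys) {
  ctr <- sdmtoolkit::grid_centers(template)
  px <- as.vector(ctr$X); py <- as.vector(ctr$Y)
  vapply(seq_along(px), function(i)
    which.min((px[i] - xs)^2 + (py[i] - ys)^2), integer(1))
}

region_cells <- function(bias) which(!is.na(as.vector(bias$values)))

rand_occ <- function(n, lim = 10, species = "sp") {
  data.frame(species = species, x = runif(n, 0, lim), y = runif(n, 0, lim))
}
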