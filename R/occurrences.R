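#' Coerce a data.frame to an occurrence set
#'
#' Occurrence sets are plain data.frames with columns `species`, `x`, `y` and
#' an optional `label` (clade/haplotype/group). Coordinates are planar map
#' units.
#'
#' @param df a data.frame with at least `species`, `x`, `y`.
#' @return The validated data.frame.
#' @export
as_occurrences <- function(df) {
  df <- as.data.frame(df)
  need <- c("species", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing occurrence columns: ", paste(miss, collapse = ", "))
  df$species <- as.character(df$species)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (any(!nzchar(df$species))) stop("species ids must be non-empty")
  if (any(!is.finite(df$x) | !is.finite(df$y)))
    stop("occurrence coordinates must be finite")
  df
}

#' Load occurrence records from CSV
#'
#' Rows with unparseable coordinates are skipped with a warning that reports
#' their line numbers; they never enter the result silently.
#'
#' @param file path to a CSV file, or ignored when `text` is given.
#' @param text optional character scalar with CSV content.
#' @param column_map named character vector mapping canonical names
#'   (`species`, `x`, `y`, `label`) to the file's column names, e.g.
#'   `c(x = "lon", y = "lat")`.
#' @return An occurrence data.frame (`species`, `x`, `y`, and `label` when
#'   mapped).
#' @export
load_occurrences <- function(file, text = NULL, column_map = NULL) {
  raw <- if (!is.null(text)) {
    utils::read.csv(text = text, stringsAsFactors = FALSE)
  } else utils::read.csv(file, stringsAsFactors = FALSE)
  cmap <- c(species = "species", x = "x", y = "y")
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  need <- c("species", "x", "y")
  miss <- need[!cmap[need] %in% names(raw)]
  if (length(miss))
    stop("CSV lacks required column(s): ", paste(cmap[miss], collapse = ", "))
  out <- data.frame(species = as.character(raw[[cmap["species"]]]),
                    x = suppressWarnings(as.numeric(raw[[cmap["x"]]])),
                    y = suppressWarnings(as.numeric(raw[[cmap["y"]]])),
                    stringsAsFactors = FALSE)
  if ("label" %in% names(cmap) && cmap["label"] %in% names(raw))
    out$label <- as.character(raw[[cmap["label"]]])
  else if ("label" %in% names(raw)) out$label <- as.character(raw$label)
  bad <- !is.finite(out$x) | !is.finite(out$y) | !nzchar(out$species)
  if (any(bad)) {
    # +1 for the header line: report file line numbers, not row indices
    warning(sprintf("skipped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  as_occurrences(out)
}

# greedy keep-first thinning of one species' points; d_i = per-point distance,
# a pair (i, j) must satisfy max(d_i, d_j)
.thin_greedy <- function(xy, d_point) {
  n <- nrow(xy)
  keep <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (k in keep) {
      lim <- max(d_point[i], d_point[k])
      if (sqrt(sum((xy[i, ] - xy[k, ])^2)) < lim) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

#' Spatially rarefy occurrence records
#'
#' Thins each species' records so that no two retained points lie closer than
#' `d` (Euclidean, map units). Thinning is greedy keep-first in input order;
#' with a `seed` the input order is first shuffled reproducibly. The result is
#' maximal: no removed point can be re-added without violating `d`.
#'
#' @param occ an occurrence data.frame.
#' @param d minimum pairwise distance in map units (`d = 0` keeps everything).
#' @param seed optional integer; when given, records are shuffled with this
#'   seed before greedy thinning.
#' @return The retained subset, in original row order.
#' @export
rarefy <- function(occ, d, seed = NULL) {
  occ <- as_occurrences(occ)
  if (!is.numeric(d) || length(d) != 1L || d < 0) stop("'d' must be >= 0")
  if (d == 0 || nrow(occ) < 2) return(occ)
  keep_rows <- logical(nrow(occ))
  for (sp in unique(occ$species)) {
    idx <- which(occ$species == sp)
    ord <- idx
    if (!is.null(seed)) {
      ord <- local({ set.seed(seed); idx[sample.int(length(idx))] })
    }
    kept <- .thin_greedy(cbind(occ$x[ord], occ$y[ord]), rep(d, length(ord)))
    keep_rows[ord[kept]] <- TRUE
  }
  out <- occ[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-distance spatial rarefaction stratified by a heterogeneity grid
#'
#' Each occurrence takes the filter distance of the heterogeneity class of the
#' cell it falls on (at most five classes). A pair of retained points spanning
#' two classes must satisfy the larger of the two distances — the conservative
#' rule, leaving fewer residual clusters. Occurrences on NoData cells get the
#' largest supplied distance, with a warning.
#'
#' @param occ an occurrence data.frame.
#' @param class_grid an `sdm_grid` of integer heterogeneity classes.
#' @param d_by_class named numeric vector: class value -> filter distance in
#'   map units (1 to 5 classes).
#' @param seed optional integer shuffle seed, as in [rarefy()].
#' @return The retained subset, in original row order.
#' @export
rarefy_multiscale <- function(occ, class_grid, d_by_class, seed = NULL) {
  occ <- as_occurrences(occ)
  stopifnot(is_grid(class_grid))
  if (length(d_by_class) < 1 || length(d_by_class) > 5)
    stop("between 1 and 5 heterogeneity classes are supported")
  if (is.null(names(d_by_class))) stop("'d_by_class' must be named by class value")
  gclasses <- unique(class_grid$values[!is.na(class_grid$values)])
  if (length(gclasses) > 5) stop("class grid holds more than 5 distinct classes")
  rc <- cell_of(class_grid, occ$x, occ$y)
  cls <- rep(NA_real_, nrow(occ))
  ok <- !is.na(rc$row)
  cls[ok] <- class_grid$values[cbind(rc$row[ok], rc$col[ok])]
  d_pt <- unname(d_by_class[as.character(cls)])
  if (anyNA(d_pt)) {
    warning(sprintf("%d occurrence(s) on NoData/unmapped class cells; using the largest filter distance %g",
                    sum(is.na(d_pt)), max(d_by_class)))
    d_pt[is.na(d_pt)] <- max(d_by_class)
  }
  keep_rows <- logical(nrow(occ))
  for (sp in unique(occ$species)) {
    idx <- which(occ$species == sp)
    ord <- idx
    if (!is.null(seed)) ord <- local({ set.seed(seed); idx[sample.int(length(idx))] })
    kept <- .thin_greedy(cbind(occ$x[ord], occ$y[ord]), d_pt[ord])
    keep_rows[ord[kept]] <- TRUE
  }
  out <- occ[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}
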