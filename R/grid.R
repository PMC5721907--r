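#' Create a raster grid
#'
#' `sdm_grid` is the package's raster container: a numeric matrix on a regular
#' square lattice with a lower-left origin. Row 1 of the matrix is the
#' northernmost row, matching the on-disk layout of ESRI ASCII grids. NoData
#' cells are held as `NA`; the `nodata` sentinel is only materialised when a
#' grid is written to disk.
#'
#' @param values numeric matrix; row 1 is the northernmost row. Cells equal to
#'   `nodata` are converted to `NA` on construction.
#' @param xll,yll x and y map coordinate of the lower-left corner of the grid.
#' @param cellsize positive cell edge length in map units (square cells).
#' @param nodata sentinel value used for NoData when writing.
#' @param crs optional opaque coordinate-system tag; carried, never interpreted.
#' @return An object of class `sdm_grid`.
#' @examples
#' g <- make_grid(matrix(1:6, 2, 3), xll = 0, yll = 0, cellsize = 10)
#' g
#' @export
make_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999, crs = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("'cellsize' must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(!is.finite(values) & !is.na(values)))
    stop("grid values must be finite or NoData")
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
         crs = crs),
    class = "sdm_grid")
}

is_grid <- function(x) inherits(x, "sdm_grid")

#' @export
print.sdm_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf("<sdm_grid> %d rows x %d cols, cellsize %g\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n", e$xmin, e$xmax, e$ymin, e$ymax))
  nd <- sum(is.na(x$values))
  cat(sprintf("  NoData cells: %d of %d (sentinel %g)\n",
              nd, length(x$values), x$nodata))
  invisible(x)
}

#' @export
summary.sdm_grid <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  cat(sprintf("sdm_grid: %d data cells", length(v)))
  if (length(v)) {
    cat(sprintf("; range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  } else cat(" (all NoData)\n")
  invisible(object)
}

#' @export
plot.sdm_grid <- function(x, ...) {
  xs <- x$xll + (seq_len(ncol(x$values)) - 0.5) * x$cellsize
  ys <- x$yll + (seq_len(nrow(x$values)) - 0.5) * x$cellsize
  # image() wants y ascending and z[x, y]; flip rows (row 1 is north)
  z <- t(x$values[rev(seq_len(nrow(x$values))), , drop = FALSE])
  graphics::image(xs, ys, z, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' @export
as.matrix.sdm_grid <- function(x, ...) x$values

#' @export
dim.sdm_grid <- function(x) dim(x$values)

#' Rectangular extent in map units
#'
#' @param xmin,ymin,xmax,ymax extent edges in map units.
#' @return An `extent_spec` object.
#' @export
extent_spec <- function(xmin, ymin, xmax, ymax) {
  if (!(xmin < xmax && ymin < ymax))
    stop("extent requires xmin < xmax and ymin < ymax")
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "extent_spec")
}

#' Extent of a grid
#' @param g an `sdm_grid`.
#' @return An `extent_spec`.
#' @export
grid_extent <- function(g) {
  extent_spec(g$xll, g$yll,
              g$xll + ncol(g$values) * g$cellsize,
              g$yll + nrow(g$values) * g$cellsize)
}

#' Cell-centre coordinates of every cell
#'
#' @param g an `sdm_grid`.
#' @return A list with matrices `X` and `Y`, same shape as `g$values`, giving
#'   the map coordinates of each cell centre.
#' @export
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  xs <- g$xll + (seq_len(nc) - 0.5) * g$cellsize
  ys <- g$yll + (nr - seq_len(nr) + 0.5) * g$cellsize  # row 1 = north
  list(X = matrix(xs, nr, nc, byrow = TRUE), Y = matrix(ys, nr, nc))
}

#' Locate the cell containing each point
#'
#' Cell ownership follows the half-open convention
#' `[x0, x0 + cellsize) x [y0, y0 + cellsize)`: a point on a shared vertical
#' edge belongs to the cell to its east, a point on a shared horizontal edge to
#' the cell to its north.
#'
#' @param g an `sdm_grid`.
#' @param x,y numeric vectors of point coordinates in map units.
#' @return A data.frame with columns `row`, `col` (NA for points outside the
#'   grid extent).
#' @export
cell_of <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$xll) / g$cellsize) + 1
  row_from_s <- floor((y - g$yll) / g$cellsize) + 1
  row <- nr - row_from_s + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) stop("grids do not share geometry (extent/cellsize)")
  invisible(TRUE)
}

# ---- ESRI ASCII I/O ---------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Accepts both `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` headers;
#' centre-referenced origins are normalised to the corner convention
#' (`corner = center - cellsize / 2`).
#'
#' @param file path to a `.asc` file, or ignored when `text` is given.
#' @param text optional character scalar holding the full file contents.
#' @return An `sdm_grid`.
#' @export
read_esri_ascii <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: fewer than 7 lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) ||
      !any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr)))
    stop("malformed ESRI ASCII header: missing required keys")
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("value count %d does not match nrows*ncols = %d",
                 length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  make_grid(m, xll = xll, yll = yll, cellsize = cs, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Always writes the corner convention (`xllcorner`/`yllcorner`); NoData cells
#' are written as the grid's sentinel. The produced text is MaxEnt-compatible.
#'
#' @param g an `sdm_grid`.
#' @param file optional output path; when omitted the text is only returned.
#' @param digits significant digits for data values.
#' @return The file text, invisibly when `file` is given.
#' @export
write_esri_ascii <- function(g, file = NULL, digits = 10) {
  stopifnot(is_grid(g))
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner %s\nyllcorner %s\ncellsize %s\nNODATA_value %s",
                 ncol(v), nrow(v),
                 format(g$xll, digits = 15), format(g$yll, digits = 15),
                 format(g$cellsize, digits = 15), format(g$nodata, digits = 15))
  body <- apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  txt <- paste0(hdr, "\n", paste(body, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

# ---- batch raster utilities -------------------------------------------------

.upscale_stats <- c("mean", "median", "majority", "minority", "min", "max", "sum")

#' Aggregate a grid to a coarser resolution
#'
#' Each output cell summarises a `factor` x `factor` block of input cells with
#' the chosen statistic, ignoring NoData; an all-NoData block stays NoData.
#' When `factor` does not divide the grid dimensions, trailing partial blocks
#' are aggregated over the cells they do contain. Majority/minority ties are
#' broken by the smallest value.
#'
#' @param g an `sdm_grid`.
#' @param factor positive integer aggregation factor.
#' @param stat one of `"mean"`, `"median"`, `"majority"`, `"minority"`,
#'   `"min"`, `"max"`, `"sum"`.
#' @return An `sdm_grid` with `cellsize * factor`.
#' @export
upscale <- function(g, factor, stat = "mean") {
  stopifnot(is_grid(g))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("'factor' must be a positive integer")
  stat <- match.arg(stat, .upscale_stats)
  if (factor == 1L) return(g)
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  onr <- ceiling(nr / factor); onc <- ceiling(nc / factor)
  f <- switch(stat,
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    min = function(x) min(x),
    max = function(x) max(x),
    sum = function(x) sum(x),
    majority = function(x) {
      tab <- table(x)
      cand <- as.numeric(names(tab)[tab == max(tab)])
      min(cand)                              # tie-break: smallest value
    },
    minority = function(x) {
      tab <- table(x)
      cand <- as.numeric(names(tab)[tab == min(tab)])
      min(cand)
    })
  out <- matrix(NA_real_, onr, onc)
  for (i in seq_len(onr)) {
    ri <- ((i - 1L) * factor + 1L):min(i * factor, nr)
    for (j in seq_len(onc)) {
      ci <- ((j - 1L) * factor + 1L):min(j * factor, nc)
      blk <- v[ri, ci]
      blk <- blk[!is.na(blk)]
      if (length(blk)) out[i, j] <- f(blk)
    }
  }
  # origin stays at the lower-left; partial blocks hang off the top/right, so
  # the top of the output lattice moves up to cover them
  ytop <- g$yll + nr * g$cellsize
  make_grid(out, xll = g$xll, yll = ytop - onr * factor * g$cellsize,
            cellsize = g$cellsize * factor, nodata = g$nodata, crs = g$crs)
}

#' Snap a set of grids to a common extent
#'
#' Expands or crops every grid to `target`; added cells are NoData, removed
#' cells are discarded, surviving data values are untouched. All grids must
#' share a cellsize and `target` must lie on each grid's lattice.
#'
#' @param grids a list of `sdm_grid` objects (a single grid is accepted).
#' @param target an `extent_spec` aligned to the shared lattice.
#' @return A list of grids with identical extent (a single grid in, single
#'   grid out).
#' @export
snap_extent <- function(grids, target) {
  single <- is_grid(grids)
  if (single) grids <- list(grids)
  stopifnot(length(grids) > 0, inherits(target, "extent_spec"))
  cs <- grids[[1]]$cellsize
  if (!all(vapply(grids, function(g) abs(g$cellsize - cs) < 1e-9, logical(1))))
    stop("all grids must share a cellsize")
  out <- lapply(grids, function(g) {
    off <- c((target$xmin - g$xll), (target$ymin - g$yll),
             (target$xmax - g$xll), (target$ymax - g$yll)) / cs
    if (any(abs(off - round(off)) > 1e-6))
      stop("target extent is not aligned to the grid lattice")
    off <- round(off)
    onc <- off[3] - off[1]; onr <- off[4] - off[2]
    nr <- nrow(g$values); nc <- ncol(g$values)
    out_v <- matrix(NA_real_, onr, onc)
    # column c_out maps to input column c_out + off[1]; rows counted from top:
    # input top row index of output row 1 is (g_top - target_top)/cs + 1
    top_shift <- round((g$yll + nr * cs - target$ymax) / cs)
    for (i in seq_len(onr)) {
      gi <- i + top_shift
      if (gi < 1 || gi > nr) next
      cols_out <- seq_len(onc)
      gcols <- cols_out + off[1]
      ok <- gcols >= 1 & gcols <= nc
      out_v[i, cols_out[ok]] <- g$values[gi, gcols[ok]]
    }
    make_grid(out_v, xll = target$xmin, yll = target$ymin, cellsize = cs,
              nodata = g$nodata, crs = g$crs)
  })
  if (single) out[[1]] else out
}

#' Redefine the NoData sentinel of a grid
#'
#' NoData cells are stored as `NA` in memory, so this changes the sentinel that
#' will be written to disk. If any data value equals the new sentinel a warning
#' reports how many cells would be coerced to NoData on a write/read roundtrip.
#'
#' @param g an `sdm_grid`.
#' @param new_sentinel replacement NoData value.
#' @return The grid with its sentinel replaced.
#' @export
redefine_nodata <- function(g, new_sentinel) {
  stopifnot(is_grid(g))
  n_collide <- sum(!is.na(g$values) & g$values == new_sentinel)
  if (n_collide > 0)
    warning(sprintf("%d data cell(s) equal the new sentinel %g and will read back as NoData",
                    n_collide, new_sentinel))
  g$nodata <- as.numeric(new_sentinel)
  g
}

#' Clip a grid to an extent or polygon
#'
#' For an `extent_spec`, the grid is cropped to the lattice-aligned bounding
#' box of the region. For a polygon (two-column matrix or data.frame of
#' vertices), the grid is cropped to the polygon's bounding box and cells whose
#' centres fall outside the polygon become NoData.
#'
#' @param g an `sdm_grid`.
#' @param region an `extent_spec`, or a polygon as a two-column (x, y) matrix.
#' @return The clipped `sdm_grid`.
#' @export
clip_grid <- function(g, region) {
  stopifnot(is_grid(g))
  nr <- nrow(g$values); nc <- ncol(g$values)
  cs <- g$cellsize
  poly <- NULL
  if (!inherits(region, "extent_spec")) {
    poly <- as.matrix(region)
    if (ncol(poly) != 2) stop("polygon region must have two columns (x, y)")
    region <- extent_spec(min(poly[, 1]), min(poly[, 2]),
                          max(poly[, 1]), max(poly[, 2]))
  }
  ge <- grid_extent(g)
  if (region$xmin >= ge$xmax || region$xmax <= ge$xmin ||
      region$ymin >= ge$ymax || region$ymax <= ge$ymin)
    stop("clip region does not overlap the grid")
  c0 <- max(1L, floor((region$xmin - g$xll) / cs) + 1L)
  c1 <- min(nc, ceiling((region$xmax - g$xll) / cs))
  rS <- max(1L, floor((region$ymin - g$yll) / cs) + 1L)   # from south
  rN <- min(nr, ceiling((region$ymax - g$yll) / cs))
  r0 <- nr - rN + 1L; r1 <- nr - rS + 1L                  # matrix rows, top-down
  v <- g$values[r0:r1, c0:c1, drop = FALSE]
  out <- make_grid(v, xll = g$xll + (c0 - 1L) * cs,
                   yll = g$yll + (rS - 1L) * cs,
                   cellsize = cs, nodata = g$nodata, crs = g$crs)
  if (!is.null(poly)) {
    ctr <- grid_centers(out)
    inside <- pracma::inpolygon(as.vector(ctr$X), as.vector(ctr$Y),
                                poly[, 1], poly[, 2])
    out$values[!matrix(inside, nrow(out$values), ncol(out$values))] <- NA_real_
  }
  out
}

#' Sample raster values at occurrence locations
#'
#' Looks up the value of the containing cell in each grid for every point.
#' Points outside the extent or on NoData cells are kept and flagged in the
#' `status` column (`"ok"`, `"outside"`, `"nodata"`), never dropped.
#'
#' @param grids a named list of `sdm_grid` objects sharing geometry.
#' @param occ an occurrence data.frame with columns `species`, `x`, `y`.
#' @return A data.frame: one row per occurrence, one column per grid, plus
#'   `status`.
#' @export
extract_values <- function(grids, occ) {
  if (is_grid(grids)) grids <- list(value = grids)
  stopifnot(length(grids) >= 1)
  if (is.null(names(grids)) || any(!nzchar(names(grids))))
    names(grids) <- paste0("layer", seq_along(grids))
  occ <- as_occurrences(occ)
  if (nrow(occ) == 0) stop("empty occurrence set")
  for (g in grids[-1]) stop_if_geometry_differs(grids[[1]], g)
  rc <- cell_of(grids[[1]], occ$x, occ$y)
  out <- occ[, c("species", "x", "y")]
  status <- ifelse(is.na(rc$row), "outside", "ok")
  for (nm in names(grids)) {
    v <- rep(NA_real_, nrow(occ))
    ok <- !is.na(rc$row)
    v[ok] <- grids[[nm]]$values[cbind(rc$row[ok], rc$col[ok])]
    status[ok & is.na(v)] <- "nodata"
    out[[nm]] <- v
  }
  out$status <- status
  out
}
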