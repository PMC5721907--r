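# Biodiversity grids from binary range stacks, and categorisation of
# Biodiverse randomisation exports (CANAPE and generic significance).

#' Validate a binary range stack
#'
#' A stack is a named list of binary `sdm_grid`s (one species each) sharing
#' geometry, with values in {0, 1, NoData}.
#'
#' @param stack named list of `sdm_grid` objects.
#' @return The validated stack.
#' @export
as_binary_stack <- function(stack) {
  if (is_grid(stack)) stack <- list(sp1 = stack)
  if (!length(stack)) stop("empty stack")
  if (is.null(names(stack)) || any(!nzchar(names(stack))))
    names(stack) <- paste0("sp", seq_along(stack))
  for (g in stack) {
    stopifnot(is_grid(g))
    stop_if_geometry_differs(stack[[1]], g)
    v <- g$values[!is.na(g$values)]
    if (any(v != 0 & v != 1)) stop("stack grids must be binary (0/1/NoData)")
  }
  stack
}

.stack_arrays <- function(stack) {
  stack <- as_binary_stack(stack)
  pres <- lapply(stack, function(g) {
    v <- g$values; v[is.na(v)] <- 0; v
  })
  any_data <- Reduce(`|`, lapply(stack, function(g) !is.na(g$values)))
  list(stack = stack, pres = pres, any_data = any_data)
}

#' Species richness grid
#'
#' Cellwise count of species present; NoData only where every layer is
#' NoData.
#'
#' @param stack a binary range stack (see [as_binary_stack()]).
#' @return An `sdm_grid` of counts.
#' @export
richness <- function(stack) {
  s <- .stack_arrays(stack)
  out <- s$stack[[1]]
  v <- Reduce(`+`, s$pres)
  v[!s$any_data] <- NA_real_
  out$values <- v
  out
}

#' Weighted endemism grid
#'
#' Each species contributes the inverse of its range size (occupied cell
#' count) to every cell it occupies, so the landscape sum of WE equals the
#' number of species exactly.
#'
#' @inheritParams richness
#' @return An `sdm_grid` of weighted endemism.
#' @export
weighted_endemism <- function(stack) {
  s <- .stack_arrays(stack)
  ranges <- vapply(s$pres, sum, numeric(1))
  if (any(ranges == 0))
    stop("species with empty range: ",
         paste(names(ranges)[ranges == 0], collapse = ", "))
  out <- s$stack[[1]]
  v <- Reduce(`+`, Map(function(p, r) p / r, s$pres, ranges))
  v[!s$any_data] <- NA_real_
  out$values <- v
  out
}

#' Corrected weighted endemism grid
#'
#' Weighted endemism divided by richness: the mean range-restriction of the
#' species present, in (0, 1]. Cells with zero richness are NoData.
#'
#' @inheritParams richness
#' @return An `sdm_grid` of corrected weighted endemism.
#' @export
corrected_weighted_endemism <- function(stack) {
  we <- weighted_endemism(stack)
  ri <- richness(stack)
  out <- we
  out$values <- ifelse(!is.na(ri$values) & ri$values > 0,
                       we$values / ri$values, NA_real_)
  out
}

#' Read a Biodiverse-style randomisation export
#'
#' @param file CSV path, or ignored when `text` is given.
#' @param text optional character scalar with CSV content.
#' @return A data.frame; columns are taken as-is (use the `columns` maps of
#'   the classification functions to point at the right fields).
#' @export
read_randomization_table <- function(file, text = NULL) {
  if (!is.null(text)) utils::read.csv(text = text, stringsAsFactors = FALSE)
  else utils::read.csv(file, stringsAsFactors = FALSE)
}

#' CANAPE categorisation of neo- and paleo-endemism
#'
#' Two-step categorical analysis of randomisation ranks exported by
#' Biodiverse. A cell is significant when the rank-p of phylogenetic endemism
#' on the original tree or on the comparison tree reaches `sig`. Among
#' significant cells: "super" when both reach `super`; otherwise "neo" when
#' the relative-PE rank-p is at or below `rpe_low` (branches significantly
#' short), "paleo" when at or above `rpe_high` (branches significantly long),
#' and "mixed" in between. Rank-p fields are the proportion of randomisations
#' in which the observed value was at least the random one.
#'
#' @param table data.frame with cell coordinates and rank-p fields.
#' @param columns named character vector mapping `x`, `y`, `p_pe_orig`,
#'   `p_pe_comp`, `p_rpe` to the table's column names (defaults follow
#'   Biodiverse export conventions).
#' @param thresholds named list overriding `sig` (0.95), `super` (0.99),
#'   `rpe_low` (0.025), `rpe_high` (0.975).
#' @param template optional `sdm_grid`; when given, a category grid is also
#'   returned (codes 0 = non-significant, 1 = neo, 2 = paleo, 3 = mixed,
#'   4 = super).
#' @return The table with a `canape` factor column; with a template, a list
#'   `list(table, grid, codes)`.
#' @export
canape_classify <- function(table,
                            columns = c(x = "Axis_0", y = "Axis_1",
                                        p_pe_orig = "P_PE_WE_P",
                                        p_pe_comp = "P_PHYLO_RPE_NULL2",
                                        p_rpe = "P_PHYLO_RPE2"),
                            thresholds = list(), template = NULL) {
  thr <- utils::modifyList(
    list(sig = 0.95, super = 0.99, rpe_low = 0.025, rpe_high = 0.975),
    thresholds)
  need <- c("p_pe_orig", "p_pe_comp", "p_rpe")
  miss <- need[!columns[need] %in% names(table)]
  if (length(miss))
    stop("randomisation table lacks column(s): ",
         paste(columns[miss], collapse = ", "))
  p_orig <- table[[columns[["p_pe_orig"]]]]
  p_comp <- table[[columns[["p_pe_comp"]]]]
  p_rpe <- table[[columns[["p_rpe"]]]]
  if (any(stats::na.omit(c(p_orig, p_comp, p_rpe)) < 0) ||
      any(stats::na.omit(c(p_orig, p_comp, p_rpe)) > 1))
    stop("rank-p fields must lie in [0, 1]")
  sig <- p_orig >= thr$sig | p_comp >= thr$sig
  cat <- rep("non-significant", nrow(table))
  cat[sig & p_orig >= thr$super & p_comp >= thr$super] <- "super"
  rest <- sig & cat != "super"
  cat[rest & p_rpe <= thr$rpe_low] <- "neo"
  cat[rest & p_rpe >= thr$rpe_high] <- "paleo"
  cat[rest & cat == "non-significant"] <- "mixed"
  lv <- c("non-significant", "neo", "paleo", "mixed", "super")
  table$canape <- factor(cat, levels = lv)
  if (is.null(template)) return(table)
  codes <- stats::setNames(0:4, lv)
  g <- template
  g$values[] <- NA_real_
  rc <- cell_of(template, table[[columns[["x"]]]], table[[columns[["y"]]]])
  ok <- !is.na(rc$row)
  g$values[cbind(rc$row[ok], rc$col[ok])] <- codes[cat[ok]]
  list(table = table, grid = g, codes = codes)
}

#' Reclassify significance of any Biodiverse randomisation field
#'
#' Generic rank-p categorisation: two-tailed marks `sig-high` at
#' `p >= 1 - alpha/2` and `sig-low` at `p <= alpha/2`; the one-tailed variants
#' use `alpha` on their single side.
#'
#' @param table data.frame holding the field.
#' @param field column name of the rank-p field.
#' @param tails `"two"`, `"one-high"` or `"one-low"`.
#' @param alpha significance level in (0, 1).
#' @return The table with a `significance` factor column
#'   (`sig-low`/`ns`/`sig-high`).
#' @export
reclassify_significance <- function(table, field, tails = c("two", "one-high",
                                                            "one-low"),
                                    alpha = 0.05) {
  tails <- match.arg(tails)
  if (!field %in% names(table)) stop("field not found: ", field)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  p <- table[[field]]
  out <- rep("ns", length(p))
  if (tails == "two") {
    out[p >= 1 - alpha / 2] <- "sig-high"
    out[p <= alpha / 2] <- "sig-low"
  } else if (tails == "one-high") {
    out[p >= 1 - alpha] <- "sig-high"
  } else {
    out[p <= alpha] <- "sig-low"
  }
  table$significance <- factor(out, levels = c("sig-low", "ns", "sig-high"))
  table
}
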