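#' Cells-by-features expression container
#'
#' A thin wrapper around a (sparse) counts or intensity matrix that
#' keeps a per-feature flag separating real genes from negative-control
#' probes, as required by the QC filter.
#'
#' @param counts cells x features matrix (base or `Matrix`), with cell
#'   ids as rownames and feature names as colnames.
#' @param is_negctrl logical per feature; defaults to matching feature
#'   names against `"^NegCtrl"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts,
                              is_negctrl = grepl("^NegCtrl",
                                                 colnames(counts))) {
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must carry cell rownames and feature colnames")
  stopifnot(length(is_negctrl) == ncol(counts))
  out <- list(counts = counts, is_negctrl = is_negctrl)
  class(out) <- "expression_matrix"
  out
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d features (%d negctrl)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_negctrl)))
  invisible(x)
}

#' QC thresholds for segmented cells
#'
#' Cell-level quality filters: area bounds (segmentation plausibility),
#' maximum fraction of counts attributable to negative-control probes,
#' and minimum number of distinct detected genes. Area defaults cover
#' the plausible single-cell range for imaging-based spatial assays and
#' are meant to be adjusted per sample.
#'
#' @param area_min_um2,area_max_um2 retained cell area range (um^2).
#' @param max_negctrl_fraction maximum tolerated negative-control count
#'   fraction, in `[0, 1]`.
#' @param min_features minimum number of distinct real genes with a
#'   nonzero count.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(area_min_um2 = 5, area_max_um2 = 700,
                          max_negctrl_fraction = 0.1, min_features = 10) {
  stopifnot(area_min_um2 < area_max_um2,
            max_negctrl_fraction >= 0, max_negctrl_fraction <= 1,
            min_features >= 0)
  out <- list(area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
              max_negctrl_fraction = max_negctrl_fraction,
              min_features = min_features)
  class(out) <- "qc_thresholds"
  out
}

#' Filter cells on area, negative-control fraction and detected genes
#'
#' Retains cells whose segmented area lies within the configured
#' bounds, whose fraction of negative-control counts does not exceed
#' the maximum, and that detect at least the minimum number of distinct
#' real genes. Rows of the cell table and expression matrix stay in
#' 1:1 correspondence. The filter is idempotent.
#'
#' @param cells cell table with `cell_id` and `area_um2` columns.
#' @param expr an [expression_matrix()] with rows matching
#'   `cells$cell_id`.
#' @param th a [qc_thresholds()].
#' @return list with filtered `cells`, `expr`, and `removed`, a named
#'   count of cells failing each criterion (a cell may fail several).
#' @export
qc_filter <- function(cells, expr, th = qc_thresholds()) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(th, "qc_thresholds"),
            all(c("cell_id", "area_um2") %in% names(cells)))
  m <- expr$counts[match(cells$cell_id, rownames(expr$counts)), ,
                   drop = FALSE]
  if (anyNA(match(cells$cell_id, rownames(expr$counts))))
    stop("cells missing from the expression matrix")
  total <- Matrix::rowSums(m)
  neg_total <- Matrix::rowSums(m[, expr$is_negctrl, drop = FALSE])
  neg_frac <- ifelse(total > 0, neg_total / total, 0)
  n_feat <- Matrix::rowSums(m[, !expr$is_negctrl, drop = FALSE] > 0)

  bad_area <- cells$area_um2 < th$area_min_um2 |
    cells$area_um2 > th$area_max_um2
  bad_neg <- neg_frac > th$max_negctrl_fraction
  bad_feat <- n_feat < th$min_features
  keep <- !(bad_area | bad_neg | bad_feat)
  if (!any(keep))
    stop("qc_filter removed all cells; relax the thresholds")
  removed <- c(area = sum(bad_area), negctrl_fraction = sum(bad_neg),
               min_features = sum(bad_feat), total = sum(!keep))
  message(sprintf(
    "qc_filter: removed %d/%d cells (area %d, negctrl %d, features %d)",
    removed["total"], nrow(cells), removed["area"],
    removed["negctrl_fraction"], removed["min_features"]))
  list(cells = cells[keep, , drop = FALSE],
       expr = expression_matrix(m[keep, , drop = FALSE], expr$is_negctrl),
       removed = removed)
}

new_norm_matrix <- function(values, method, params) {
  out <- list(values = values, method = method, params = params)
  class(out) <- "norm_matrix"
  out
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix (%s): %d cells x %d features\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Shifted logarithmic normalization of counts
#'
#' Rescales each cell's counts to a fixed total (the scaling factor,
#' default 300) and applies `log1p`:
#' `value(c, g) = ln(1 + count(c, g) * scale / total(c))`.
#' Proportion-preserving, so doubling all counts of a cell leaves its
#' normalized profile unchanged.
#'
#' @param expr an [expression_matrix()] of counts.
#' @param scale scaling factor applied to per-cell proportions.
#' @param include_negctrl include negative-control probes in the output
#'   (they always contribute to the per-cell total).
#' @return a `norm_matrix` with method `"shifted_log"`.
#' @export
shifted_log_normalize <- function(expr, scale = 300,
                                  include_negctrl = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"), scale > 0)
  total <- Matrix::rowSums(expr$counts)
  if (any(total == 0))
    stop("zero-total cells: ",
         paste(head(rownames(expr$counts)[total == 0], 5), collapse = ", "))
  m <- expr$counts
  if (!include_negctrl) m <- m[, !expr$is_negctrl, drop = FALSE]
  v <- log1p(as.matrix(m) * (scale / total))
  new_norm_matrix(v, "shifted_log", list(scale = scale))
}

#' Inverse hyperbolic sine transform
#'
#' `asinh(x / cofactor)`, the standard variance-compressing transform
#' for mass-cytometry intensities; strictly monotone and odd.
#'
#' @param values numeric matrix of intensities (cells x markers).
#' @param cofactor positive scaling cofactor (default 1).
#' @return a `norm_matrix` with method `"arcsinh"`.
#' @export
arcsinh_transform <- function(values, cofactor = 1) {
  stopifnot(is.numeric(cofactor), cofactor > 0)
  new_norm_matrix(asinh(as.matrix(values) / cofactor), "arcsinh",
                  list(cofactor = cofactor))
}

#' Feature-wise z-score against a reference subset
#'
#' Per feature, subtracts the mean and divides by the (n-1) standard
#' deviation of the reference rows. In the mass-cytometry pipeline the
#' transform is applied twice: first with the whole dataset as
#' reference, then restricted to the fibroblasts. When `groups` is
#' supplied, standardization is computed independently within each
#' group (per-sample scaling).
#'
#' @param values numeric matrix or `norm_matrix` (cells x features).
#' @param reference_rows indices or logical mask of reference rows
#'   (default: all rows).
#' @param groups optional per-row grouping factor; standardization is
#'   applied within each group independently.
#' @return a `norm_matrix` with method `"zscore"`.
#' @export
zscore <- function(values, reference_rows = NULL, groups = NULL) {
  if (inherits(values, "norm_matrix")) values <- values$values
  values <- as.matrix(values)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(values))
    out <- values
    for (g in unique(groups)) {
      sel <- which(groups == g)
      ref <- if (is.null(reference_rows)) sel
             else intersect(sel, normalize_ref(reference_rows, nrow(values)))
      out[sel, ] <- zscore_block(values[sel, , drop = FALSE],
                                 match(ref, sel))
    }
    return(new_norm_matrix(out, "zscore", list(per_group = TRUE)))
  }
  ref <- if (is.null(reference_rows)) seq_len(nrow(values))
         else normalize_ref(reference_rows, nrow(values))
  new_norm_matrix(zscore_block(values, ref), "zscore",
                  list(n_reference = length(ref)))
}

normalize_ref <- function(reference_rows, n) {
  if (is.logical(reference_rows)) which(reference_rows)
  else as.integer(reference_rows)
}

zscore_block <- function(values, ref) {
  if (length(ref) < 2) stop("reference must contain at least 2 rows")
  mu <- colMeans(values[ref, , drop = FALSE])
  sdv <- apply(values[ref, , drop = FALSE], 2L, sd)
  if (any(sdv == 0))
    stop("zero-variance features in reference: ",
         paste(colnames(values)[sdv == 0], collapse = ", "))
  sweep(sweep(values, 2L, mu, "-"), 2L, sdv, "/")
}
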