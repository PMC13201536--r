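#' Truncated mean
#'
#' Drops `floor(trim * n)` smallest and largest values and averages the
#' rest (10% trimming at both ends by default).
#'
#' @param x numeric vector (nonempty).
#' @param trim trimming fraction in `[0, 0.5)`.
#' @return the truncated mean.
#' @export
truncated_mean <- function(x, trim = 0.10) {
  if (!length(x)) stop("empty vector")
  stopifnot(trim >= 0, trim < 0.5)
  n <- length(x)
  k <- floor(trim * n)
  if (k == 0) return(mean(x))
  mean(sort(x)[(k + 1):(n - k)])
}

#' Spatially constrained ligand-receptor interaction scores
#'
#' For every ordered source/target cell-type combination and
#' ligand-receptor pair, expression is summarized by the truncated
#' mean (10% at both ends) of the ligand over source cells and of the
#' receptor over target cells; the interaction score is their product,
#' gated by a hard spatial mask: the score is emitted as nonzero only
#' when at least one source-target cell pair lies within the mode's
#' maximum distance (250 um for secreted, 20 um for contact-dependent
#' signaling). Types with fewer than `min_cells` cells are skipped
#' entirely. The admissible-pair fraction is reported for filtering.
#'
#' @param cells cell table with `cell_id`, `x_um`, `y_um` and a type
#'   column.
#' @param norm cells x genes matrix or `norm_matrix`, rows aligned
#'   with `cells`.
#' @param pairs data.frame with columns `ligand`, `receptor`, `mode`
#'   (`"secreted"` or `"contact"`).
#' @param d_secreted_um,d_contact_um distance cutoffs (defaults 250 and
#'   20 um).
#' @param min_cells minimum cells per participating type (default 10).
#' @param trim trimming fraction for the truncated mean (default 0.10).
#' @param type_col column holding cell-type labels.
#' @return data.frame with `source`, `target`, `ligand`, `receptor`,
#'   `mode`, `eligible_fraction`, `score`.
#' @export
spatial_lr_score <- function(cells, norm, pairs, d_secreted_um = 250,
                             d_contact_um = 20, min_cells = 10,
                             trim = 0.10, type_col = "true_type") {
  values <- if (inherits(norm, "norm_matrix")) norm$values else
    as.matrix(norm)
  stopifnot(nrow(values) == nrow(cells),
            all(c("ligand", "receptor", "mode") %in% names(pairs)),
            all(pairs$mode %in% c("secreted", "contact")))
  known <- pairs$ligand %in% colnames(values) &
    pairs$receptor %in% colnames(values)
  if (any(!known)) {
    warning("skipping pairs with unknown genes: ",
            paste(pairs$ligand[!known], pairs$receptor[!known],
                  sep = "-", collapse = ", "))
    pairs <- pairs[known, , drop = FALSE]
  }
  types <- names(which(table(cells[[type_col]]) >= min_cells))
  pts <- as.matrix(cells[, c("x_um", "y_um")])
  out <- list()
  for (src in types) {
    si <- which(cells[[type_col]] == src)
    for (tgt in types) {
      ti <- which(cells[[type_col]] == tgt)
      d <- cross_dist(pts[si, , drop = FALSE], pts[ti, , drop = FALSE])
      for (pi in seq_len(nrow(pairs))) {
        cutoff <- if (pairs$mode[pi] == "secreted") d_secreted_um
                  else d_contact_um
        elig <- mean(d <= cutoff)
        score <- if (elig > 0) {
          truncated_mean(values[si, pairs$ligand[pi]], trim) *
            truncated_mean(values[ti, pairs$receptor[pi]], trim)
        } else 0
        out[[length(out) + 1L]] <- data.frame(
          source = src, target = tgt,
          ligand = pairs$ligand[pi], receptor = pairs$receptor[pi],
          mode = pairs$mode[pi], eligible_fraction = elig,
          score = max(0, score))
      }
    }
  }
  if (!length(out))
    return(data.frame(source = character(0), target = character(0),
                      ligand = character(0), receptor = character(0),
                      mode = character(0),
                      eligible_fraction = numeric(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

#' Sum interaction scores into user-defined pathways
#'
#' @param scores output of [spatial_lr_score()].
#' @param pathway_map data.frame with `ligand`, `receptor`, `pathway`.
#' @return data.frame of summed scores per source, target and pathway.
#' @export
aggregate_pathways <- function(scores, pathway_map) {
  stopifnot(all(c("ligand", "receptor", "pathway") %in%
                  names(pathway_map)))
  key <- paste(scores$ligand, scores$receptor)
  mkey <- paste(pathway_map$ligand, pathway_map$receptor)
  scores$pathway <- pathway_map$pathway[match(key, mkey)]
  scores <- scores[!is.na(scores$pathway), , drop = FALSE]
  agg <- aggregate(score ~ source + target + pathway, scores, sum)
  agg
}
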