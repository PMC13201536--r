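#' Marker gating rule
#'
#' One node of a gating hierarchy: a label plus marker conditions on
#' z-scored intensities. Relations and default thresholds: `"+"` means
#' z > 0, `"high"` z > 1, `"-"` z <= 0, `"low"` z <= 1; each condition
#' may override its threshold. A rule with no conditions acts as a
#' residual catch-all.
#'
#' @param label type label assigned when all conditions hold.
#' @param conditions list of lists with fields `marker`, `relation`
#'   (one of `+`, `-`, `high`, `low`) and optional `threshold`.
#' @return an object of class `gating_rule`.
#' @export
gating_rule <- function(label, conditions = list()) {
  defaults <- c(`+` = 0, high = 1, `-` = 0, low = 1)
  conditions <- lapply(conditions, function(cnd) {
    stopifnot(!is.null(cnd$marker), cnd$relation %in% names(defaults))
    cnd$threshold <- cnd$threshold %||% unname(defaults[cnd$relation])
    cnd
  })
  out <- list(label = label, conditions = conditions)
  class(out) <- "gating_rule"
  out
}

#' The mass-cytometry skin gating hierarchy
#'
#' Evaluation order: epithelial cells (E-cadherin+), then immune cells
#' (CD45+, E-cadherin-), endothelial cells (CD31+, E-cadherin-),
#' vascular smooth muscle cells (SM22 high, aSMA high, E-cadherin-),
#' with fibroblasts as the residual (CD45-, CD31-, E-cadherin-,
#' SM22 low/-, aSMA low/-). Every cell receives exactly one label.
#'
#' @return list of [gating_rule()] objects in evaluation order.
#' @export
default_gating_rules <- function() {
  list(
    gating_rule("epithelial", list(
      list(marker = "Ecadherin", relation = "+"))),
    gating_rule("immune", list(
      list(marker = "Ecadherin", relation = "-"),
      list(marker = "CD45", relation = "+"))),
    gating_rule("endothelial", list(
      list(marker = "Ecadherin", relation = "-"),
      list(marker = "CD45", relation = "-"),
      list(marker = "CD31", relation = "+"))),
    gating_rule("vsmc", list(
      list(marker = "Ecadherin", relation = "-"),
      list(marker = "CD45", relation = "-"),
      list(marker = "CD31", relation = "-"),
      list(marker = "SM22", relation = "high"),
      list(marker = "aSMA", relation = "high"))),
    gating_rule("fibroblast"))
}

#' Assign one leaf label per cell by sequential gating
#'
#' Rules are evaluated in order; the first rule whose conditions all
#' hold labels the cell. The final rule is expected to be a residual
#' (no conditions) so that the labels partition all cells.
#'
#' @param norm a `norm_matrix` of z-scored intensities, or a plain
#'   matrix (cells x markers).
#' @param rules list of [gating_rule()]s, e.g.
#'   [default_gating_rules()].
#' @return character vector of labels, one per cell.
#' @export
gate_cells <- function(norm, rules = default_gating_rules()) {
  values <- if (inherits(norm, "norm_matrix")) norm$values else
    as.matrix(norm)
  markers <- unique(unlist(lapply(rules, function(r)
    vapply(r$conditions, function(cnd) cnd$marker, ""))))
  missing <- setdiff(markers, colnames(values))
  if (length(missing))
    stop("markers missing from panel: ", paste(missing, collapse = ", "))
  labels <- rep(NA_character_, nrow(values))
  for (rule in rules) {
    ok <- rep(TRUE, nrow(values))
    for (cnd in rule$conditions) {
      z <- values[, cnd$marker]
      ok <- ok & switch(cnd$relation,
        `+` = z > cnd$threshold, high = z > cnd$threshold,
        `-` = z <= cnd$threshold, low = z <= cnd$threshold)
    }
    labels[is.na(labels) & ok] <- rule$label
  }
  if (anyNA(labels))
    stop("gating rules do not cover all cells; add a residual rule")
  labels
}

#' Graph-based clustering of cells in marker space
#'
#' Builds the exact Euclidean k-nearest-neighbour graph on the feature
#' matrix and partitions it by modularity-based Leiden community
#' detection. Deterministic given `seed`. The default resolution (0.1)
#' is chosen so that homogeneous, well-separated groups come out as
#' single communities rather than being fragmented by the modularity
#' optimiser; merging of near-duplicate communities remains a manual,
#' user-driven step (see `merge_map`).
#'
#' @param features cells x markers matrix or `norm_matrix`.
#' @param k_neighbors number of nearest neighbours for the graph.
#' @param seed integer seed (mandatory).
#' @param resolution Leiden modularity resolution.
#' @param merge_map optional named vector mapping raw cluster labels to
#'   merged labels, mirroring the manual merging of over-clustered
#'   groups.
#' @return integer (or merged) cluster labels, one per cell.
#' @export
cluster_cells <- function(features, k_neighbors, seed,
                          resolution = 0.1, merge_map = NULL) {
  values <- if (inherits(features, "norm_matrix")) features$values else
    as.matrix(features)
  n <- nrow(values)
  if (n <= k_neighbors)
    stop("need more cells than k_neighbors")
  nn <- knn_indices(values, k_neighbors)
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                    directed = FALSE))
  cl <- with_seed(seed,
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10))
  labels <- as.integer(igraph::membership(cl))
  if (!is.null(merge_map)) {
    mapped <- merge_map[as.character(labels)]
    labels <- ifelse(is.na(mapped), as.character(labels), mapped)
  }
  labels
}

#' k-nearest-neighbour label transfer between datasets
#'
#' Labels each query cell by the majority vote of its `k` nearest
#' reference cells in a shared (identically normalized) feature space,
#' Euclidean metric. Ties are broken toward the lexicographically
#' smallest label and flagged.
#'
#' @param ref_features,ref_labels reference matrix and labels.
#' @param query_features query matrix with the same columns.
#' @param k number of neighbours (default 10).
#' @return data.frame with `label`, `vote_fraction` (>= 1/k) and `tie`.
#' @export
knn_label_transfer <- function(ref_features, ref_labels, query_features,
                               k = 10) {
  ref <- as.matrix(ref_features); qry <- as.matrix(query_features)
  stopifnot(ncol(ref) == ncol(qry), length(ref_labels) == nrow(ref))
  if (k > nrow(ref)) stop("k exceeds the reference size")
  d <- cross_dist(qry, ref)
  res <- apply(d, 1L, function(row) {
    nb <- order(row)[seq_len(k)]
    tab <- sort(table(ref_labels[nb]), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    list(label = sort(names(top))[1],
         vote = unname(tab[1]) / k,
         tie = length(top) > 1)
  })
  data.frame(label = vapply(res, `[[`, "", "label"),
             vote_fraction = vapply(res, `[[`, 0, "vote"),
             tie = vapply(res, `[[`, TRUE, "tie"))
}

#' Filter a label-correspondence table for spurious pairs
#'
#' Keeps label pairs supported by at least `min_cells` cells and by at
#' least `min_fraction` of the source label's total.
#'
#' @param mapping_counts data.frame with columns `source`, `target`,
#'   `count`.
#' @param min_cells minimum absolute pair count (default 50).
#' @param min_fraction minimum share of the source label (default 0.10).
#' @return the filtered data.frame with an added `fraction` column.
#' @export
filter_correspondence <- function(mapping_counts, min_cells = 50,
                                  min_fraction = 0.10) {
  stopifnot(all(c("source", "target", "count") %in%
                  names(mapping_counts)),
            all(mapping_counts$count >= 0))
  totals <- tapply(mapping_counts$count, mapping_counts$source, sum)
  frac <- mapping_counts$count /
    as.numeric(totals[as.character(mapping_counts$source)])
  keep <- mapping_counts$count >= min_cells & frac >= min_fraction
  out <- mapping_counts[keep, , drop = FALSE]
  out$fraction <- frac[keep]
  out
}
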