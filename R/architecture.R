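#' Detect the epidermal layer from keratinocyte patches
#'
#' Keratinocytes are linked when closer than `link_radius_um`;
#' connected components with at least `min_patch` members are candidate
#' patches, and those lying above the dermis (mean depth smaller than
#' the mean depth of non-keratinocyte cells) are labeled epidermis.
#' Mid-dermal keratinocyte structures (hair follicles) are thereby
#' excluded.
#'
#' @param cells cell table with `cell_id`, `x_um`, `y_um` and a type
#'   column.
#' @param link_radius_um linkage radius for patch construction.
#' @param min_patch minimum keratinocytes per patch (default 10).
#' @param type_col column holding cell-type labels.
#' @param keratinocyte_types labels treated as keratinocytes.
#' @return an `epidermis_model`: list with `cell_ids` and `points`
#'   (members x 2 coordinate matrix).
#' @export
detect_epidermis <- function(cells, link_radius_um = 30, min_patch = 10,
                             type_col = "true_type",
                             keratinocyte_types = c("keratinocyte",
                                                    "epithelial")) {
  stopifnot(link_radius_um > 0,
            all(c("cell_id", "x_um", "y_um", type_col) %in% names(cells)))
  is_ker <- cells[[type_col]] %in% keratinocyte_types
  ker <- cells[is_ker, , drop = FALSE]
  if (nrow(ker) == 0) stop("no epidermal layer found")
  pts <- as.matrix(ker[, c("x_um", "y_um")])
  d <- cross_dist(pts, pts)
  adj <- d <= link_radius_um
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep_comp <- which(sizes >= min_patch)
  if (!length(keep_comp)) stop("no epidermal layer found")
  dermal_depth <- mean(cells$y_um[!is_ker])
  if (!is.finite(dermal_depth)) dermal_depth <- Inf
  epi_comp <- keep_comp[vapply(keep_comp, function(ci)
    mean(ker$y_um[comp$membership == ci]) < dermal_depth, TRUE)]
  if (!length(epi_comp)) stop("no epidermal layer found")
  sel <- comp$membership %in% epi_comp
  out <- list(cell_ids = ker$cell_id[sel],
              points = pts[sel, , drop = FALSE])
  class(out) <- "epidermis_model"
  out
}

#' Distance from each cell to the epidermal layer
#'
#' Euclidean distance from each cell centroid to the nearest member of
#' the epidermis model; epidermal members get distance 0.
#'
#' @param cells cell table with `cell_id`, `x_um`, `y_um`.
#' @param epi an `epidermis_model` from [detect_epidermis()].
#' @return numeric vector of distances (um), named by cell id.
#' @export
distance_to_epidermis <- function(cells, epi) {
  stopifnot(inherits(epi, "epidermis_model"),
            nrow(epi$points) > 0)
  pts <- as.matrix(cells[, c("x_um", "y_um")])
  out <- numeric(nrow(cells))
  idx <- seq_len(nrow(cells))
  for (chunk in split(idx, ceiling(idx / 500))) {
    d <- cross_dist(pts[chunk, , drop = FALSE], epi$points)
    out[chunk] <- apply(d, 1L, min)
  }
  out[cells$cell_id %in% epi$cell_ids] <- 0
  setNames(out, cells$cell_id)
}

#' Papillary/reticular compartment from epidermis distance
#'
#' Distances strictly below the border (default 100 um) are papillary;
#' at or beyond the border, reticular (the boundary value itself is
#' reticular, by documented convention).
#'
#' @param distance_um non-negative distances to the epidermis.
#' @param border_um papillary/reticular frontier (default 100 um).
#' @return character vector, `"papillary"` or `"reticular"`.
#' @export
assign_compartment <- function(distance_um, border_um = 100) {
  if (any(distance_um < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  ifelse(distance_um < border_um, "papillary", "reticular")
}

#' Detect vessel patches among papillary endothelial cells
#'
#' Builds a knn-reachability graph on the supplied cells (expected to
#' be the endothelial cells of the papillary dermis): cells i and j are
#' linked when one is among the other's `k` nearest neighbours and
#' their distance does not exceed `max_link_um` (the distance cap keeps
#' the neighbourhood spatially local; without it, small distant vessels
#' would be linked purely by rank). Connected components with at least
#' `min_size` members become patches.
#'
#' @param cells cell table restricted to papillary endothelial cells.
#' @param k neighbours per cell (default 10).
#' @param min_size minimum cells per patch (default 3).
#' @param max_link_um maximum link distance in um (default 30).
#' @return list of `vessel_patch` objects (fields `cell_ids`,
#'   `centroid`, `coords`); empty list when fewer than `min_size` cells
#'   are supplied.
#' @export
detect_vessel_patches <- function(cells, k = 10, min_size = 3,
                                  max_link_um = 30) {
  n <- nrow(cells)
  if (n < min_size) return(list())
  pts <- as.matrix(cells[, c("x_um", "y_um")])
  kk <- min(k, n - 1L)
  nn <- knn_indices(pts, kk)
  d <- cross_dist(pts, pts)
  edges <- cbind(rep(seq_len(n), each = kk), as.vector(t(nn)))
  dist_ok <- d[edges] <= max_link_um
  edges <- edges[dist_ok, , drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                    directed = FALSE))
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  out <- list()
  for (ci in which(comp$csize >= min_size)) {
    sel <- comp$membership == ci
    patch <- list(cell_ids = cells$cell_id[sel],
                  coords = pts[sel, , drop = FALSE],
                  centroid = colMeans(pts[sel, , drop = FALSE]))
    class(patch) <- "vessel_patch"
    out[[length(out) + 1L]] <- patch
  }
  out
}

# First principal axis (unit vector) of a 2-column coordinate matrix.
principal_axis <- function(coords) {
  cc <- sweep(coords, 2L, colMeans(coords))
  if (all(abs(cc) < 1e-12))
    stop("degenerate patch: all points identical")
  sv <- svd(cc)
  sv$v[, 1L]
}

#' Orientation of a vessel patch relative to the epidermis
#'
#' Fits the patch's long axis as the first principal component of its
#' member coordinates, fits the local epidermis axis from epidermal
#' points within `local_radius_um` of the patch centroid (falling back
#' to the global epidermis axis with a warning when fewer than two
#' local points exist), and reports the acute angle between the two
#' axes. Patches at more than 45 degrees are flagged perpendicular
#' (strict inequality: exactly 45 is not flagged).
#'
#' @param patch a `vessel_patch` from [detect_vessel_patches()].
#' @param epi an `epidermis_model`.
#' @param local_radius_um radius for the local epidermis reference line.
#' @return the patch with added `angle_deg` (in `[0, 90]`),
#'   `perpendicular` flag and `axis`.
#' @export
patch_orientation <- function(patch, epi, local_radius_um = 200) {
  stopifnot(inherits(patch, "vessel_patch"),
            inherits(epi, "epidermis_model"))
  if (nrow(patch$coords) < 3) stop("patch must have at least 3 cells")
  axis_p <- principal_axis(patch$coords)
  d <- cross_dist(matrix(patch$centroid, 1L), epi$points)[1L, ]
  local <- epi$points[d <= local_radius_um, , drop = FALSE]
  if (nrow(local) < 2) {
    warning("no local epidermis near patch; using global epidermis axis")
    local <- epi$points
  }
  axis_e <- principal_axis(local)
  ang <- acos(pmin(1, abs(sum(axis_p * axis_e)))) * 180 / pi
  ang <- round(ang, 9)  # snap away sub-nano-degree rounding noise
  patch$angle_deg <- ang
  patch$perpendicular <- ang > 45
  patch$axis <- axis_p
  patch
}

#' Weighted Gaussian kernel density map
#'
#' Evaluates `sum_i w_i * K_h(||p - p_i||)` with isotropic Gaussian
#' kernels of bandwidth `bandwidth_um` on a regular grid that extends
#' `4 * bandwidth` beyond the data, so the Riemann sum of the map
#' recovers the total weight.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param weights per-cell weights (finite); default 1.
#' @param bandwidth_um kernel standard deviation in um (default 50).
#' @param grid_spacing_um grid resolution in um (default 10).
#' @return a `density_map`: list with grid vectors `x`, `y`, matrix
#'   `z` (x by y), `bandwidth_um`, `grid_spacing_um`.
#' @export
kde_map <- function(cells, weights = NULL, bandwidth_um = 50,
                    grid_spacing_um = 10) {
  stopifnot(bandwidth_um > 0, grid_spacing_um > 0)
  x <- cells$x_um; y <- cells$y_um
  w <- weights %||% rep(1, length(x))
  if (any(!is.finite(w))) stop("weights must be finite")
  pad <- 4 * bandwidth_um
  gx <- seq(min(x) - pad, max(x) + pad, by = grid_spacing_um)
  gy <- seq(min(y) - pad, max(y) + pad, by = grid_spacing_um)
  kx <- dnorm(outer(gx, x, "-"), sd = bandwidth_um)
  ky <- dnorm(outer(gy, y, "-"), sd = bandwidth_um)
  z <- kx %*% (w * t(ky))
  out <- list(x = gx, y = gy, z = z, bandwidth_um = bandwidth_um,
              grid_spacing_um = grid_spacing_um)
  class(out) <- "density_map"
  out
}
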