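contour_vertices <- function(contour) {
  if (inherits(contour, "interface_contour")) return(contour$vertices)
  stopifnot(all(c("x_um", "y_um", "label") %in% names(contour)))
  contour
}

contour_width_mm <- function(contour, width_mm = NULL) {
  if (!is.null(width_mm)) return(width_mm)
  if (inherits(contour, "interface_contour")) return(contour$width_mm)
  v <- contour_vertices(contour)
  diff(range(v$x_um)) / 1000
}

#' Dermal papillae per millimetre of section
#'
#' Number of labeled papilla apexes divided by the section width.
#'
#' @param contour an `interface_contour` or a data.frame with
#'   `x_um`, `y_um`, `label`.
#' @param width_mm section width override (mm).
#' @return papillae per mm.
#' @export
papillae_per_mm <- function(contour, width_mm = NULL) {
  w <- contour_width_mm(contour, width_mm)
  if (!is.finite(w) || w <= 0) stop("section width must be positive")
  sum(contour_vertices(contour)$label == "apex") / w
}

#' Rete ridges per millimetre of section
#'
#' @inheritParams papillae_per_mm
#' @return ridge vertices per mm.
#' @export
rete_ridges_per_mm <- function(contour, width_mm = NULL) {
  w <- contour_width_mm(contour, width_mm)
  if (!is.finite(w) || w <= 0) stop("section width must be positive")
  sum(contour_vertices(contour)$label == "ridge") / w
}

#' Perpendicular papilla height over its base line
#'
#' The papilla base is the line through the two rete ridges flanking
#' the papilla; the height is the perpendicular (point-to-line)
#' distance from the apex to that infinite line. Invariant under rigid
#' motions of the three points.
#'
#' @param apex,ridge_left,ridge_right length-2 numeric points (um).
#' @return height in um.
#' @export
papilla_height <- function(apex, ridge_left, ridge_right) {
  base <- ridge_right - ridge_left
  nb <- sqrt(sum(base^2))
  if (nb < 1e-12) stop("ridge points coincide")
  v <- apex - ridge_left
  abs(base[1] * v[2] - base[2] * v[1]) / nb
}

#' Heights of every papilla along a labeled contour
#'
#' For each apex, finds the nearest ridge vertices on either side and
#' applies [papilla_height()]. Apexes lacking a flanking ridge are
#' skipped.
#'
#' @inheritParams papillae_per_mm
#' @return numeric vector of heights (um), one per measurable papilla.
#' @export
contour_papilla_heights <- function(contour) {
  v <- contour_vertices(contour)
  v <- v[order(v$x_um), , drop = FALSE]
  apexes <- which(v$label == "apex")
  ridges <- which(v$label == "ridge")
  out <- numeric(0)
  for (ai in apexes) {
    left <- ridges[ridges < ai]
    right <- ridges[ridges > ai]
    if (!length(left) || !length(right)) next
    out <- c(out, papilla_height(
      c(v$x_um[ai], v$y_um[ai]),
      c(v$x_um[max(left)], v$y_um[max(left)]),
      c(v$x_um[min(right)], v$y_um[min(right)])))
  }
  out
}

#' Fold change of a follow-up measurement over baseline
#'
#' @param value_followup follow-up measurement.
#' @param value_baseline baseline measurement (> 0).
#' @return ratio follow-up / baseline.
#' @export
normalize_to_baseline <- function(value_followup, value_baseline) {
  if (any(value_baseline <= 0)) stop("baseline must be positive")
  value_followup / value_baseline
}

#' Collagen fiber alignment coefficient
#'
#' The circular resultant length of the doubled orientation angles:
#' `c = |mean_i (cos 2 theta_i, sin 2 theta_i)|`, mapping perfect
#' parallelism (all angles equal mod 180 degrees) to 1 and isotropy to
#' 0. For fibers whose doubled angles follow a von Mises distribution
#' with concentration kappa, the expected coefficient is the Bessel
#' ratio `I1(kappa)/I0(kappa)`. Invariant under global rotation and
#' under `theta -> theta + 180`.
#'
#' @param angles_deg fiber orientations in degrees, interpreted mod
#'   180.
#' @return coefficient in `[0, 1]`.
#' @export
alignment_coefficient <- function(angles_deg) {
  if (!length(angles_deg)) stop("empty orientation sample")
  a <- 2 * angles_deg * pi / 180
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

#' Median alignment coefficient across regions of interest
#'
#' Computes the coefficient per ROI and returns the median, matching
#' the reporting convention of three ROIs per skin section.
#'
#' @param roi_angles list of per-ROI angle vectors (degrees).
#' @return median coefficient.
#' @export
alignment_coefficient_median <- function(roi_angles) {
  stopifnot(is.list(roi_angles), length(roi_angles) > 0)
  stats::median(vapply(roi_angles, alignment_coefficient, 0))
}
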