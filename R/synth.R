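#' Configuration for the synthetic skin tissue generator
#'
#' Describes a rectangular skin section in tissue coordinates where `y`
#' increases downward from the surface (depth, in micrometers). The
#' dermal-epidermal interface follows `y = e + A * sin(2*pi*x / P)` with
#' epidermis thickness `e`, papilla amplitude `A` and period `P`; cells
#' are placed uniformly within their compartment, vessels as elongated
#' point clouds of endothelial cells at a controlled orientation, and
#' expression counts are drawn from a negative binomial with per-type
#' marker enrichments and a planted post-treatment shift.
#'
#' @param width_um,height_um section extent in micrometers.
#' @param papilla_amplitude_um,papilla_period_um interface undulation
#'   amplitude and period; amplitude 0 gives a flat interface.
#' @param epidermis_thickness_um mean depth of the interface; must
#'   exceed the papilla amplitude so the interface stays below surface.
#' @param samples data.frame with columns `sample`, `timepoint`.
#' @param cells_per_type data.frame with columns `type`, `compartment`
#'   (one of `"epidermis"`, `"papillary"`, `"reticular"`) and `n`, the
#'   exact number of cells planted per sample.
#' @param vessel_specs list of vessel descriptions, each a list with
#'   `n_cells`, `centroid` (x, y in um), `orientation_deg` (0 =
#'   parallel to the surface, 90 = perpendicular), `length_um`, and
#'   optionally `sample` (defaults to the first sample).
#' @param genes_background number of unstructured background genes.
#' @param n_negctrl number of negative-control probes.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and
#'   dispersion (size) for real genes.
#' @param negctrl_rate Poisson rate for negative-control probes.
#' @param marker_log2fc data.frame `type`, `gene`, `log2fc` giving
#'   cell-type marker enrichments.
#' @param treatment_log2fc named numeric vector: planted expression
#'   shift (log2 fold change) applied to cells of treated time points.
#' @param treated_timepoints time points receiving the treatment shift;
#'   defaults to every time point other than `"baseline"`.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `tissue_config`.
#' @export
tissue_config <- function(width_um = 2000, height_um = 1000,
                          papilla_amplitude_um = 30,
                          papilla_period_um = 250,
                          epidermis_thickness_um = 40,
                          samples = data.frame(
                            sample = c("BL_1", "M12_1"),
                            timepoint = c("baseline", "12mo")),
                          cells_per_type = default_cells_per_type(),
                          vessel_specs = list(),
                          genes_background = 20,
                          n_negctrl = 10,
                          nb_mean = 2, nb_dispersion = 2,
                          negctrl_rate = 0.05,
                          marker_log2fc = default_marker_log2fc(),
                          treatment_log2fc = default_treatment_log2fc(),
                          treated_timepoints = NULL,
                          seed = 1L) {
  stopifnot(width_um > 0, height_um > 0, papilla_period_um > 0,
            epidermis_thickness_um > 0, nb_mean > 0, nb_dispersion > 0,
            negctrl_rate >= 0)
  if (papilla_amplitude_um < 0) stop("papilla amplitude must be >= 0")
  if (papilla_amplitude_um > 0 && papilla_period_um >= width_um)
    stop("papilla_period_um must be smaller than width_um")
  if (papilla_amplitude_um >= epidermis_thickness_um)
    stop("papilla amplitude must be smaller than the epidermis thickness")
  if (height_um < epidermis_thickness_um + papilla_amplitude_um + 150)
    stop("tissue too shallow for a reticular compartment")
  stopifnot(all(c("sample", "timepoint") %in% names(samples)),
            all(c("type", "compartment", "n") %in% names(cells_per_type)),
            all(cells_per_type$n >= 0))
  if (!all(cells_per_type$compartment %in%
             c("epidermis", "papillary", "reticular")))
    stop("unknown compartment in cells_per_type")
  cfg <- list(width_um = width_um, height_um = height_um,
              papilla_amplitude_um = papilla_amplitude_um,
              papilla_period_um = papilla_period_um,
              epidermis_thickness_um = epidermis_thickness_um,
              samples = samples, cells_per_type = cells_per_type,
              vessel_specs = vessel_specs,
              genes_background = genes_background,
              n_negctrl = n_negctrl,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              negctrl_rate = negctrl_rate,
              marker_log2fc = marker_log2fc,
              treatment_log2fc = treatment_log2fc,
              treated_timepoints = treated_timepoints %||%
                setdiff(unique(samples$timepoint), "baseline"),
              seed = as.integer(seed))
  class(cfg) <- "tissue_config"
  cfg
}

#' @rdname tissue_config
#' @export
default_cells_per_type <- function() {
  data.frame(
    type = c("keratinocyte", "fibroblast", "endothelial", "immune",
             "fibroblast", "endothelial", "immune"),
    compartment = c("epidermis", "papillary", "papillary", "papillary",
                    "reticular", "reticular", "reticular"),
    n = c(400, 300, 60, 40, 500, 40, 60))
}

#' @rdname tissue_config
#' @export
default_marker_log2fc <- function() {
  data.frame(
    type = c("keratinocyte", "keratinocyte", "fibroblast", "fibroblast",
             "endothelial", "endothelial", "immune", "immune"),
    gene = c("KRT14", "KRT5", "COL1A1", "LUM", "PECAM1", "VWF",
             "PTPRC", "CD3E"),
    log2fc = c(3, 2.5, 3, 2.5, 3, 2.5, 3, 2.5))
}

#' @rdname tissue_config
#' @export
default_treatment_log2fc <- function() {
  c(EGFL7 = 1, ANGPT2 = 1, PI16 = 1, KRT6A = 1,
    FAP = -1, COL8A1 = -1, SFRP2 = -1, CCL19 = -1)
}

# Depth of the dermal-epidermal interface at horizontal position x.
interface_depth <- function(cfg, x) {
  cfg$epidermis_thickness_um +
    cfg$papilla_amplitude_um * sin(2 * pi * x / cfg$papilla_period_um)
}

# Minimum Euclidean distance from points to the interface curve,
# evaluated against a dense polyline sampling (0.5 um steps).
interface_distance <- function(cfg, x, y, step_um = 0.5) {
  gx <- seq(0, cfg$width_um, by = step_um)
  gy <- interface_depth(cfg, gx)
  pts <- cbind(x, y)
  out <- numeric(length(x))
  idx <- seq_along(x)
  for (chunk in split(idx, ceiling(idx / 500))) {
    d <- cross_dist(pts[chunk, , drop = FALSE], cbind(gx, gy))
    out[chunk] <- apply(d, 1L, min)
  }
  out
}

#' Generate a synthetic skin tissue section with ground truth
#'
#' Places cells by exact count within the epidermis, papillary and
#' reticular strata, adds vessels as elongated endothelial point
#' clouds, and draws negative-binomial expression with marker and
#' treatment shifts. Deterministic given `config$seed`.
#'
#' @param config a [tissue_config()].
#' @return a list with elements `cells` (data.frame: `cell_id`,
#'   `sample`, `timepoint`, `x_um`, `y_um`, `area_um2`, `true_type`),
#'   `expr` (an [expression_matrix()] of cells x genes counts) and
#'   `truth` (ground truth: per-cell compartment and interface
#'   distance, papilla count and heights, vessel membership and
#'   orientation, per-sample composition, the planted signature and a
#'   DEG table realising it).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(config$seed, generate_tissue_impl(config))
}

generate_tissue_impl <- function(cfg) {
  rows <- list()
  vessel_members <- list()
  first_sample <- cfg$samples$sample[1L]

  for (si in seq_len(nrow(cfg$samples))) {
    smp <- cfg$samples$sample[si]
    tp <- cfg$samples$timepoint[si]
    for (ci in seq_len(nrow(cfg$cells_per_type))) {
      n <- cfg$cells_per_type$n[ci]
      if (n == 0) next
      comp <- cfg$cells_per_type$compartment[ci]
      x <- runif(n, 0, cfg$width_um)
      yi <- interface_depth(cfg, x)
      y <- switch(comp,
        epidermis = runif(n, 0, yi),
        papillary = yi + runif(n, 0.5, 99.5),
        reticular = yi + runif(n, 100.5, pmax(101, cfg$height_um - yi)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, timepoint = tp, x_um = x, y_um = y,
        true_type = cfg$cells_per_type$type[ci])
    }
  }

  for (vi in seq_along(cfg$vessel_specs)) {
    vs <- cfg$vessel_specs[[vi]]
    stopifnot(!is.null(vs$n_cells), !is.null(vs$centroid),
              !is.null(vs$orientation_deg), !is.null(vs$length_um))
    ang <- vs$orientation_deg * pi / 180
    dir <- c(cos(ang), sin(ang))
    ends <- rbind(vs$centroid - dir * vs$length_um / 2,
                  vs$centroid + dir * vs$length_um / 2)
    if (any(ends[, 1] < 0 | ends[, 1] > cfg$width_um |
              ends[, 2] < 0 | ends[, 2] > cfg$height_um))
      stop(sprintf("vessel spec %d extends outside tissue bounds", vi))
    n <- vs$n_cells
    t_along <- seq(-vs$length_um / 2, vs$length_um / 2, length.out = n) +
      rnorm(n, 0, 2)
    perp <- rnorm(n, 0, 1.5)
    x <- vs$centroid[1] + t_along * dir[1] - perp * dir[2]
    y <- vs$centroid[2] + t_along * dir[2] + perp * dir[1]
    smp <- vs$sample %||% first_sample
    tp <- cfg$samples$timepoint[match(smp, cfg$samples$sample)]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = smp, timepoint = tp, x_um = x, y_um = y,
      true_type = "endothelial")
    vessel_members[[vi]] <- length(rows)  # placeholder, resolved below
  }

  cells <- do.call(rbind, rows)
  cells$cell_id <- sprintf("cell_%05d", seq_len(nrow(cells)))
  cells$area_um2 <- rlnorm(nrow(cells), log(100), 0.3)
  cells <- cells[, c("cell_id", "sample", "timepoint", "x_um", "y_um",
                     "area_um2", "true_type")]

  # resolve vessel membership: rows were appended block-wise
  block_sizes <- vapply(rows, nrow, 0L)
  block_end <- cumsum(block_sizes)
  vessels <- NULL
  if (length(cfg$vessel_specs)) {
    membership <- lapply(seq_along(cfg$vessel_specs), function(vi) {
      bi <- vessel_members[[vi]]
      cells$cell_id[(block_end[bi] - block_sizes[bi] + 1L):block_end[bi]]
    })
    vessels <- list(
      orientation_deg = vapply(cfg$vessel_specs,
                               function(v) v$orientation_deg, 0),
      members = membership)
  }

  # ground truth geometry
  yi <- interface_depth(cfg, cells$x_um)
  is_epi <- cells$y_um < yi
  dist_um <- rep(NA_real_, nrow(cells))
  dist_um[!is_epi] <- interface_distance(cfg, cells$x_um[!is_epi],
                                         cells$y_um[!is_epi])
  comp <- ifelse(is_epi, "epidermis",
                 ifelse(dist_um < 100, "papillary", "reticular"))

  expr <- generate_expression(cfg, cells)

  composition <- table(cells$sample, cells$true_type)

  n_pap <- if (cfg$papilla_amplitude_um > 0)
    as.integer(cfg$width_um %/% cfg$papilla_period_um) else 0L

  sig <- cfg$treatment_log2fc
  panel <- colnames(expr$counts)[!expr$is_negctrl]
  deg <- data.frame(gene = panel,
                    log2fc = ifelse(panel %in% names(sig),
                                    sig[panel], 0),
                    padj = ifelse(panel %in% names(sig), 1e-6,
                                  runif(length(panel), 0.2, 1)))
  rownames(deg) <- NULL

  truth <- list(
    true_compartment = setNames(comp, cells$cell_id),
    true_distance_um = setNames(dist_um, cells$cell_id),
    true_papilla_count = n_pap,
    true_papilla_heights = rep(cfg$papilla_amplitude_um, n_pap),
    vessels = vessels,
    true_composition = composition,
    true_signature = sig,
    deg_table = deg)

  list(cells = cells, expr = expr, truth = truth)
}

# Negative-binomial counts for real genes, Poisson for negative
# controls; marker and treatment effects act multiplicatively on the
# mean (2^log2fc).
generate_expression <- function(cfg, cells) {
  sig_genes <- names(cfg$treatment_log2fc)
  marker_genes <- unique(cfg$marker_log2fc$gene)
  bg <- sprintf("BG%03d", seq_len(cfg$genes_background))
  genes <- unique(c(marker_genes, sig_genes, bg))
  negctrl <- sprintf("NegCtrl%02d", seq_len(cfg$n_negctrl))
  n <- nrow(cells)
  treated <- cells$timepoint %in% cfg$treated_timepoints

  lfc <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  for (mi in seq_len(nrow(cfg$marker_log2fc))) {
    sel <- cells$true_type == cfg$marker_log2fc$type[mi]
    lfc[sel, cfg$marker_log2fc$gene[mi]] <-
      lfc[sel, cfg$marker_log2fc$gene[mi]] + cfg$marker_log2fc$log2fc[mi]
  }
  if (length(sig_genes))
    lfc[treated, sig_genes] <- lfc[treated, sig_genes] +
      rep(cfg$treatment_log2fc, each = sum(treated))

  mu <- cfg$nb_mean * 2^lfc
  counts <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu),
                   n, length(genes))
  nc <- matrix(rpois(n * cfg$n_negctrl, cfg$negctrl_rate),
               n, cfg$n_negctrl)
  all_counts <- cbind(counts, nc)
  dimnames(all_counts) <- list(cells$cell_id, c(genes, negctrl))
  expression_matrix(Matrix::Matrix(all_counts, sparse = TRUE),
                    is_negctrl = c(rep(FALSE, length(genes)),
                                   rep(TRUE, length(negctrl))))
}

#' Construct an annotated dermal-epidermal interface contour
#'
#' Builds an ordered polyline for a section whose interface carries
#' `n_papillae` papillae of the given amplitude and period. Rete-ridge
#' vertices sit at multiples of the period (depth = base), papilla
#' apexes halfway between them (depth = base - amplitude), following
#' the downward-increasing depth convention. With a flat base every
#' papilla height equals the amplitude exactly.
#'
#' @param n_papillae number of papillae (>= 0); 0 gives a flat segment.
#' @param amplitude_um papilla amplitude (>= 0).
#' @param period_um horizontal period of the papillae.
#' @param base_depth_um depth of the rete-ridge line.
#' @param points_per_period polyline sampling density (even integer).
#' @return an object of class `interface_contour`: list with `vertices`
#'   (data.frame `x_um`, `y_um`, `label` in apex/ridge/plain) and
#'   `width_mm`, the section width.
#' @export
generate_interface_contour <- function(n_papillae, amplitude_um,
                                       period_um, base_depth_um = 100,
                                       points_per_period = 20) {
  if (n_papillae < 0 || n_papillae != round(n_papillae))
    stop("n_papillae must be a non-negative integer")
  if (amplitude_um < 0) stop("amplitude must be non-negative")
  stopifnot(period_um > 0)
  if (n_papillae == 0) {
    v <- data.frame(x_um = c(0, period_um),
                    y_um = rep(base_depth_um, 2),
                    label = c("ridge", "plain"))
    out <- list(vertices = v, width_mm = period_um / 1000)
    class(out) <- "interface_contour"
    return(out)
  }
  pp <- max(2L, 2L * round(points_per_period / 2))
  x <- seq(0, n_papillae * period_um, by = period_um / pp)
  y <- base_depth_um - amplitude_um * (1 - cos(2 * pi * x / period_um)) / 2
  k <- round(x / period_um * pp)   # index within period grid
  label <- rep("plain", length(x))
  label[k %% pp == 0] <- "ridge"
  label[k %% pp == pp / 2] <- "apex"
  out <- list(vertices = data.frame(x_um = x, y_um = y, label = label),
              width_mm = n_papillae * period_um / 1000)
  class(out) <- "interface_contour"
  out
}

# von Mises sampler (Best & Fisher 1979), mean 0, concentration kappa,
# support (-pi, pi].
rvonmises <- function(n, kappa) {
  if (kappa < 1e-9) return(runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 16L
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    out <- c(out, theta[ok])
  }
  out[seq_len(n)]
}

#' Draw a fiber orientation field with controlled alignment
#'
#' Samples `n` axial orientations in `[0, 180)` degrees such that the
#' doubled angles `2*theta` follow a von Mises distribution with mean
#' `2*mu_deg` and concentration `kappa`. `kappa = 0` yields isotropic
#' fibers (alignment coefficient near 0); large `kappa` yields near
#' perfect parallelism (coefficient near 1); in general the expected
#' alignment coefficient is the Bessel ratio `I1(kappa)/I0(kappa)`.
#'
#' @param n number of fibers.
#' @param kappa von Mises concentration of the doubled angles (>= 0).
#' @param mu_deg mean orientation in degrees.
#' @param seed optional integer seed.
#' @return numeric vector of angles in `[0, 180)` degrees.
#' @export
generate_orientation_field <- function(n, kappa, mu_deg = 0, seed = NULL) {
  stopifnot(n > 0, kappa >= 0)
  with_seed(seed, {
    phi <- rvonmises(n, kappa)      # doubled-angle deviation, radians
    (mu_deg + phi * 90 / pi) %% 180
  })
}
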