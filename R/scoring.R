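#' Build signature weights from a differential-expression table
#'
#' Keeps genes below the adjusted-p cutoff and uses their log2 fold
#' changes as weights (the "mode of regulation" of the response
#' score).
#'
#' @param deg_table data.frame with columns `gene`, `log2fc`, `padj`.
#' @param padj_max adjusted-p cutoff (default 0.05).
#' @return named numeric vector of weights.
#' @export
build_signature <- function(deg_table, padj_max = 0.05) {
  if (is.null(deg_table) || nrow(deg_table) == 0)
    stop("empty DEG table")
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(deg_table)))
  dup <- deg_table$gene[duplicated(deg_table$gene)]
  if (length(dup))
    stop("duplicate genes in DEG table: ",
         paste(unique(dup), collapse = ", "))
  keep <- deg_table$padj < padj_max
  if (sum(keep) < 3)
    stop("fewer than 3 genes pass the adjusted-p cutoff")
  setNames(deg_table$log2fc[keep], deg_table$gene[keep])
}

ulm_t <- function(y, w) {
  n <- length(y)
  r <- suppressWarnings(stats::cor(y, w))
  if (!is.finite(r)) return(list(t = 0, saturated = FALSE))
  if (1 - r^2 < 1e-12)
    return(list(t = sign(r) * 1e6, saturated = TRUE))
  list(t = r * sqrt((n - 2) / (1 - r^2)), saturated = FALSE)
}

#' Signature activity as the t-statistic of a univariate linear model
#'
#' Regresses a cell's expression profile on the signature weights
#' (ordinary least squares with intercept, over the genes shared by
#' profile and signature) and returns the t-statistic of the slope.
#' The score is invariant to positive affine rescaling of the weights
#' and flips sign under weight negation. When the fit is exact
#' (residual variance ~ 0) the score saturates at +/- 1e6 and is
#' flagged via the `"saturated"` attribute.
#'
#' @param cell_profile named numeric expression vector of one cell.
#' @param sig named weight vector from [build_signature()].
#' @return scalar score with attribute `saturated`.
#' @seealso [ulm_scores()] for the vectorized many-cell version.
#' @export
ulm_score <- function(cell_profile, sig) {
  shared <- intersect(names(cell_profile), names(sig))
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between profile and signature")
  w <- sig[shared]
  if (stats::var(w) == 0) stop("signature weights have zero variance")
  res <- ulm_t(as.numeric(cell_profile[shared]), as.numeric(w))
  structure(res$t, saturated = res$saturated)
}

#' @rdname ulm_score
#' @param values cells x genes matrix (or `norm_matrix`).
#' @export
ulm_scores <- function(values, sig) {
  if (inherits(values, "norm_matrix")) values <- values$values
  shared <- intersect(colnames(values), names(sig))
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between matrix and signature")
  w <- as.numeric(sig[shared])
  if (stats::var(w) == 0) stop("signature weights have zero variance")
  y <- values[, shared, drop = FALSE]
  n <- length(w)
  wc <- w - mean(w)
  yc <- y - rowMeans(y)
  num <- as.numeric(yc %*% wc)
  den <- sqrt(rowSums(yc^2)) * sqrt(sum(wc^2))
  r <- ifelse(den > 0, num / den, 0)
  sat <- 1 - r^2 < 1e-12
  t <- ifelse(sat, sign(r) * 1e6, r * sqrt((n - 2) / (1 - r^2)))
  structure(setNames(t, rownames(values)), saturated = sat)
}

#' Module score against bin-matched control genes
#'
#' Genes are binned by their average expression across cells
#' (equal-frequency bins); each signature gene contributes `n_ctrl`
#' control genes sampled from its bin, and the score of a cell is the
#' mean expression of the gene set minus the mean expression of the
#' pooled controls. Deterministic given `seed`.
#'
#' @param norm cells x genes matrix or `norm_matrix`.
#' @param genes character vector of set members.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl controls sampled per set gene (default 100; bins
#'   smaller than this are sampled with replacement, with a warning).
#' @param seed integer seed.
#' @return per-cell numeric score.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  values <- if (inherits(norm, "norm_matrix")) norm$values else
    as.matrix(norm)
  set <- intersect(genes, colnames(values))
  if (!length(set)) stop("gene set has no overlap with the panel")
  avg <- colMeans(values)
  nb <- min(n_bins, ncol(values))
  bin <- if (nb == 1) rep(1L, ncol(values)) else
    as.integer(cut(rank(avg, ties.method = "first"),
                   breaks = nb, labels = FALSE))
  names(bin) <- colnames(values)
  ctrl <- with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- setdiff(names(bin)[bin == bin[g]], set)
      if (!length(pool)) pool <- names(bin)[bin == bin[g]]
      if (length(pool) < n_ctrl) {
        warning(sprintf(
          "bin of gene %s has %d genes < n_ctrl; sampling with replacement",
          g, length(pool)))
        sample(pool, n_ctrl, replace = TRUE)
      } else sample(pool, n_ctrl)
    }))
  })
  set_mean <- rowMeans(values[, set, drop = FALSE])
  ctrl_mean <- rowMeans(values[, ctrl, drop = FALSE])
  setNames(set_mean - ctrl_mean, rownames(values))
}

#' Gene-set activity as area under the recovery curve (AUCell)
#'
#' Ranks genes by decreasing expression (ties broken by gene name),
#' truncates the ranking at `ceiling(top_fraction * G)`, and reports
#' the area under the set-recovery step curve normalized by its
#' maximum attainable value, giving a score in `[0, 1]`.
#'
#' @param profile named numeric expression vector (a cell or a
#'   pseudobulk profile).
#' @param genes character vector of set members.
#' @param top_fraction fraction of top ranks integrated (default 0.05).
#' @return scalar in `[0, 1]`.
#' @export
aucell <- function(profile, genes, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  g_all <- names(profile)
  if (length(genes) > length(g_all))
    stop("gene set larger than the panel")
  set <- intersect(genes, g_all)
  if (!length(set)) stop("gene set has no overlap with the panel")
  ord <- order(-as.numeric(profile), g_all)
  ranked <- g_all[ord]
  max_rank <- ceiling(top_fraction * length(g_all))
  hits <- ranked[seq_len(max_rank)] %in% set
  cum_hits <- cumsum(hits)
  auc <- sum(cum_hits)
  max_auc <- sum(pmin(seq_len(max_rank), length(set)))
  auc / max_auc
}

# Weighted Kolmogorov-Smirnov enrichment score from sorted hit
# positions. `absr_p` is |stat|^p over the full ranking (used when
# weight_p > 0), `pos` a k x n matrix of sorted positions (each column
# one gene set placement), `G` the ranking length.
es_from_positions <- function(pos, absr_p, G, weight_p) {
  pos <- as.matrix(pos)
  k <- nrow(pos); n <- ncol(pos)
  if (weight_p == 0) {
    w <- matrix(1, k, n)
  } else {
    w <- matrix(absr_p[pos], k, n)
  }
  nr <- colSums(w)
  zero <- nr == 0
  if (any(zero)) { w[, zero] <- 1; nr[zero] <- k }
  cs <- apply(w, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = k)
  cs <- sweep(cs, 2L, nr, "/")
  miss <- 1 / (G - k)
  m <- (pos - seq_len(k)) * miss
  after <- cs - m
  before <- rbind(0, cs[-k, , drop = FALSE]) - m
  cand <- rbind(after, before)
  pick <- max.col(t(abs(cand)), ties.method = "first")
  cand[cbind(pick, seq_len(n))]
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score of a gene
#' set on a ranked statistic (hit increments proportional to
#' `|stat|^weight_p`, miss decrements `1/(G - |S|)`), normalizes it by
#' the mean absolute same-sign permutation score (NES), and reports a
#' +1-corrected permutation p-value from the same-sign tail. The null
#' permutes gene labels (random sets of equal size).
#'
#' @param ranked named numeric vector of per-gene statistics.
#' @param genes character vector of set members (>= 2 shared).
#' @param weight_p enrichment weighting exponent (default 1).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return an `enrichment_result`: list with `es`, `nes`, `p`,
#'   `n_perm`, `size` and the permutation scores `perm_es`.
#' @export
preranked_gsea <- function(ranked, genes, weight_p = 1, n_perm = 1000,
                           seed = 1L) {
  stopifnot(n_perm >= 100)
  if (length(unique(ranked)) == 1L)
    stop("all statistics equal: no ranking")
  ord <- order(-as.numeric(ranked), names(ranked))
  nm <- names(ranked)[ord]
  G <- length(nm)
  pos_obs <- which(nm %in% genes)
  k <- length(pos_obs)
  if (k < 1) stop("no set genes in the ranking")
  if (k >= G) stop("gene set covers the whole ranking")
  absr_p <- abs(as.numeric(ranked)[ord])^weight_p
  es <- es_from_positions(matrix(pos_obs, ncol = 1), absr_p, G, weight_p)
  perm <- with_seed(seed, {
    p <- vapply(seq_len(n_perm),
                function(i) sort(sample.int(G, k)), integer(k))
    es_from_positions(p, absr_p, G, weight_p)
  })
  same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
  p_val <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  out <- list(es = unname(es), nes = unname(nes), p = p_val,
              n_perm = n_perm, size = k, perm_es = perm)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES = %.4f  NES = %.4f  p = %.4g  (|S| = %d, %d perms)\n",
              x$es, x$nes, x$p, x$size, x$n_perm))
  invisible(x)
}

#' Same-sign FDR over a batch of enrichment results
#'
#' The GSEA-style q-value: for each set, the fraction of pooled
#' same-sign permutation NES at least as extreme as the set's NES,
#' divided by the corresponding fraction among the observed NES,
#' clipped to `[0, 1]`.
#'
#' @param results list of `enrichment_result`s scored on the same
#'   ranking.
#' @return numeric vector of q-values.
#' @export
gsea_fdr <- function(results) {
  nes_obs <- vapply(results, function(r) r$nes, 0)
  perm_nes <- unlist(lapply(results, function(r) {
    pos <- r$perm_es[r$perm_es >= 0]; neg <- r$perm_es[r$perm_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }))
  vapply(seq_along(results), function(i) {
    ni <- nes_obs[i]
    if (!is.finite(ni)) return(NA_real_)
    if (ni >= 0) {
      num <- mean(perm_nes[perm_nes >= 0] >= ni)
      den <- mean(nes_obs[nes_obs >= 0] >= ni)
    } else {
      num <- mean(perm_nes[perm_nes < 0] <= ni)
      den <- mean(nes_obs[nes_obs < 0] <= ni)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
}

#' Pseudobulk aggregation of a normalized matrix
#'
#' Per-group arithmetic mean of each gene, for groups defined by any
#' per-cell factor (typically the sample x cell-type interaction).
#'
#' @param norm cells x genes matrix or `norm_matrix`.
#' @param groups per-cell grouping vector or factor.
#' @return groups x genes matrix of means.
#' @export
pseudobulk <- function(norm, groups) {
  values <- if (inherits(norm, "norm_matrix")) norm$values else
    as.matrix(norm)
  stopifnot(length(groups) == nrow(values))
  groups <- as.character(groups)
  sums <- rowsum(values, groups)
  sums / as.vector(table(groups)[rownames(sums)])
}
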