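# Shared fixtures, built in code at test time.

# A small single-sample tissue for fast module tests.
small_tissue_config <- function(seed = 7L, vessel_specs = list(),
                                amplitude = 30) {
  tissue_config(
    width_um = 1000, height_um = 600,
    papilla_amplitude_um = amplitude, papilla_period_um = 250,
    epidermis_thickness_um = 40,
    samples = data.frame(sample = "S1", timepoint = "baseline"),
    cells_per_type = data.frame(
      type = c("keratinocyte", "fibroblast", "endothelial",
               "fibroblast", "endothelial"),
      compartment = c("epidermis", "papillary", "papillary",
                      "reticular", "reticular"),
      n = c(150, 80, 20, 120, 15)),
    vessel_specs = vessel_specs,
    seed = seed)
}

# Two well-separated Gaussian blobs, the clustering oracle fixture.
two_blob_features <- function(n = 200, sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
             cbind(rnorm(n, sep, sd), rnorm(n, sep, sd)))
  rownames(x) <- sprintf("c%03d", seq_len(2 * n))
  list(features = x, truth = rep(c(1L, 2L), each = n))
}

# Horizontal line of epidermal reference cells at depth y0.
epi_line <- function(n = 101, width = 1000, y0 = 40) {
  data.frame(cell_id = sprintf("epi%03d", seq_len(n)),
             x_um = seq(0, width, length.out = n), y_um = y0,
             true_type = "keratinocyte")
}

# Brute-force connected components under the vessel-patch edge rule
# (knn-or-reachability with a distance cap); independent of igraph.
brute_patch_components <- function(pts, k, max_link) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  kk <- min(k, n - 1L)
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(kk)]))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- TRUE
  adj <- (adj | t(adj)) & d <= max_link
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# O(G) cumulative-walk enrichment score, the hand-walk GSEA oracle.
walk_es <- function(stats, genes, weight_p = 1) {
  ord <- order(-stats, names(stats))
  nm <- names(stats)[ord]
  r <- abs(stats[ord])^weight_p
  hit <- nm %in% genes
  inc <- ifelse(hit, r / sum(r[hit]), 0)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  w <- cumsum(inc - dec)
  w[which.max(abs(w))]
}

expect_setequal_ids <- function(a, b) expect_setequal(a, b)
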