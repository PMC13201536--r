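# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pairwise Euclidean distances between rows of two matrices (n x 2, m x 2).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Indices of the k nearest neighbours of each row of `x` among rows of `x`
# (self excluded). Brute force; fine for the tissue sizes handled here.
knn_indices <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of points")
  d <- cross_dist(x, x)
  diag(d) <- Inf
  t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni-corrected per-test significance threshold
#'
#' Divides the family-wise significance level by the number of
#' comparisons, the correction used for the histology group contrasts
#' (four follow-up comparisons give 0.0125; two give 0.025).
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param n_tests number of comparisons in the family.
#' @return the per-test threshold `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 4) # 0.0125
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (missing(n_tests) || n_tests < 1 || n_tests != round(n_tests))
    stop("n_tests must be a positive integer")
  alpha / n_tests
}
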