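#' Cross-tabulate cells into a sample-by-type composition table
#'
#' @param cells cell table carrying sample and type labels.
#' @param sample_col,type_col column names (defaults `sample`,
#'   `true_type`).
#' @return integer matrix, samples x cell types.
#' @export
count_composition <- function(cells, sample_col = "sample",
                              type_col = "true_type") {
  if (nrow(cells) == 0)
    return(matrix(integer(0), 0, 0))
  tab <- table(cells[[sample_col]], cells[[type_col]])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

# One condition's posterior draws of type proportions: hierarchical
# Dirichlet resampling. For each posterior draw, samples (with
# replacement) are drawn from the condition's samples, a Dirichlet
# (counts + prior) is drawn per selected sample, and the sample-level
# proportions are averaged. Captures both within-sample multinomial
# noise and between-sample variability.
dirichlet_condition_draws <- function(counts, n_draws, prior) {
  s <- nrow(counts); k <- ncol(counts)
  alpha <- counts + prior
  boot <- matrix(sample.int(s, n_draws * s, replace = TRUE), n_draws, s)
  idx <- as.vector(t(boot))
  shapes <- alpha[idx, , drop = FALSE]
  g <- matrix(rgamma(length(shapes), shape = shapes), nrow(shapes), k)
  p <- g / rowSums(g)
  pm <- rowsum(p, rep(seq_len(n_draws), each = s)) / s
  colnames(pm) <- colnames(counts)
  pm
}

#' Bayesian Dirichlet-multinomial compositional contrast
#'
#' Detects cell-type composition shifts between two conditions. Per
#' condition, the posterior of type proportions is approximated by
#' hierarchical resampling of per-sample Dirichlet draws (Jeffreys
#' prior 1/2 per type). The effect per type is the posterior mean
#' difference of logit proportions, `E[logit pi_b - logit pi_a]`, with
#' a 95% credible interval. Significance follows the minimum-effect /
#' FDR decision rule: the per-type tail probability
#' `P(|delta| <= effect_min)` is converted to a local-FDR-style q by
#' the running mean of sorted tail probabilities, and a type is called
#' significant when `q < fdr_max` and `|effect| > effect_min`.
#'
#' @param tab samples x types count matrix from [count_composition()].
#' @param conditions named vector mapping sample (rowname) to
#'   condition.
#' @param condition_a,condition_b the two condition labels; effects
#'   are reported as b relative to a.
#' @param n_draws posterior draws (>= 1000; default 4000).
#' @param effect_min minimum effect size on the logit scale (default
#'   0.1).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param prior Dirichlet prior mass per type (default 1/2, Jeffreys).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return data.frame with one row per type: `effect`, `lo`, `hi`
#'   (2.5/97.5% credible bounds), `tail_prob`, `q`, `significant`.
#' @export
dm_contrast <- function(tab, conditions, condition_a, condition_b,
                        n_draws = 4000, effect_min = 0.1,
                        fdr_max = 0.05, prior = 0.5, seed = 1L) {
  stopifnot(n_draws >= 1000, effect_min >= 0)
  conditions <- conditions[rownames(tab)]
  sel_a <- which(conditions == condition_a)
  sel_b <- which(conditions == condition_b)
  if (!length(sel_a) || !length(sel_b))
    stop("both conditions must be present in the table")
  absent <- colSums(tab[c(sel_a, sel_b), , drop = FALSE]) == 0
  if (any(absent)) {
    warning("types absent from both conditions dropped: ",
            paste(colnames(tab)[absent], collapse = ", "))
    tab <- tab[, !absent, drop = FALSE]
  }
  with_seed(seed, {
    pa <- dirichlet_condition_draws(tab[sel_a, , drop = FALSE],
                                    n_draws, prior)
    pb <- dirichlet_condition_draws(tab[sel_b, , drop = FALSE],
                                    n_draws, prior)
    delta <- logit(pb) - logit(pa)
    effect <- colMeans(delta)
    ci <- apply(delta, 2L, quantile, probs = c(0.025, 0.975))
    tail_prob <- colMeans(abs(delta) <= effect_min)
    ord <- order(tail_prob)
    q <- numeric(length(tail_prob))
    q[ord] <- cumsum(tail_prob[ord]) / seq_along(ord)
    data.frame(type = colnames(tab), effect = effect,
               lo = ci[1, ], hi = ci[2, ], tail_prob = tail_prob,
               q = q,
               significant = q < fdr_max & abs(effect) > effect_min,
               row.names = NULL)
  })
}
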