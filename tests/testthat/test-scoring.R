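test_that("build_signature applies the adjusted-p cutoff", {
  deg <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(1, -2, 0.5, 3),
                    padj = c(0.01, 0.04, 0.049, 0.06))
  sig <- build_signature(deg)
  expect_setequal(names(sig), c("A", "B", "C"))
  expect_error(build_signature(deg[0, ]), "empty")
  expect_error(build_signature(rbind(deg, deg[1, ])), "duplicate.*A")
  expect_error(build_signature(deg[c(1, 4), ]), "fewer than 3")
})

test_that("ulm score equals the normal-equations t oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- 20
    w <- rnorm(n); names(w) <- sprintf("g%02d", 1:n)
    y <- rnorm(n); names(y) <- names(w)
    got <- ulm_score(y, w)
    # independent oracle: solve the normal equations directly
    X <- cbind(1, w)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(as.numeric(got), as.numeric(beta[2] / se),
                 tolerance = 1e-8)
  }
})

test_that("ulm score invariances and saturation", {
  set.seed(32)
  n <- 50
  w <- rnorm(n); names(w) <- sprintf("g%02d", 1:n)
  y <- rnorm(n); names(y) <- names(w)
  base <- as.numeric(ulm_score(y, w))
  expect_equal(as.numeric(ulm_score(y, 3 * w + 7)), base,
               tolerance = 1e-10)
  expect_equal(as.numeric(ulm_score(y, -w)), -base, tolerance = 1e-10)
  # orthogonal response: score near zero
  y_orth <- y - w * sum(y * (w - mean(w))) / sum((w - mean(w))^2)
  y_orth <- y_orth - mean(y_orth) + mean(y)
  expect_lt(abs(as.numeric(ulm_score(y_orth, w))), 1e-6)
  # exact fit saturates positively
  sat <- ulm_score(setNames(2 * w, names(w)), w)
  expect_identical(as.numeric(sat), 1e6)
  expect_true(attr(sat, "saturated"))
  expect_error(ulm_score(y, setNames(rep(1, n), names(w))),
               "zero variance")
})

test_that("vectorized ulm agrees with the single-profile path", {
  set.seed(33)
  w <- setNames(rnorm(15), sprintf("g%02d", 1:15))
  m <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(sprintf("c%d", 1:10), names(w)))
  sc <- ulm_scores(m, w)
  for (i in 1:10)
    expect_equal(unname(sc[i]), as.numeric(ulm_score(m[i, ], w)),
                 tolerance = 1e-10)
})

test_that("module score separates planted shifts from nulls", {
  set.seed(34)
  ncell <- 40; G <- 300
  base <- matrix(rnorm(ncell * G, 0, 0.1), ncell, G,
                 dimnames = list(sprintf("c%d", 1:ncell),
                                 sprintf("g%03d", 1:G)))
  set_genes <- sprintf("g%03d", 1:10)
  # null: set genes indistinguishable from bin-mates; small bins
  # trigger the documented with-replacement warning
  expect_warning(module_score(base, set_genes[1], seed = 2),
                 "replacement")
  s0 <- suppressWarnings(module_score(base, set_genes, seed = 2))
  expect_lt(max(abs(s0)), 0.2)
  # planted: set genes 1 above everything, single bin
  shifted <- base
  shifted[, set_genes] <- shifted[, set_genes] + 1
  s1 <- module_score(shifted, set_genes, n_bins = 1, seed = 2)
  expect_equal(unname(s1), rep(1, ncell), tolerance = 0.1)
  expect_error(module_score(base, c("zz1", "zz2")), "no overlap")
})

test_that("aucell matches the exhaustive recovery-curve oracle", {
  set.seed(35)
  G <- 100
  prof <- setNames(rnorm(G), sprintf("g%03d", 1:G))
  genes <- sample(names(prof), 10)
  got <- aucell(prof, genes, top_fraction = 0.2)
  # brute force: walk the ranking, integrate the step curve
  ranked <- names(prof)[order(-prof, names(prof))]
  max_rank <- ceiling(0.2 * G)
  cum <- 0; auc <- 0
  for (i in seq_len(max_rank)) {
    if (ranked[i] %in% genes) cum <- cum + 1
    auc <- auc + cum
  }
  oracle <- auc / sum(pmin(seq_len(max_rank), length(genes)))
  expect_equal(got, oracle, tolerance = 1e-12)
  # extremes
  top <- setNames(c(rep(10, 5), rnorm(G - 5)), names(prof))
  expect_equal(aucell(top, names(prof)[1:5], 0.2), 1)
  bottom <- setNames(c(rep(-10, 5), rnorm(G - 5)), names(prof))
  expect_equal(aucell(bottom, names(prof)[1:5], 0.05), 0)
  expect_error(aucell(prof, c(names(prof), "extra")), "larger")
})

test_that("aucell is monotone in top-ranked additions", {
  set.seed(36)
  prof <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  genes <- sample(names(prof)[11:100], 10)
  top_gene <- names(prof)[order(-prof)][1]
  expect_gte(aucell(prof, c(genes, top_gene), 0.3),
             aucell(prof, genes, 0.3))
})

test_that("enrichment scores match the cumulative-walk oracle", {
  set.seed(37)
  G <- 100
  stats <- setNames(rnorm(G), sprintf("g%03d", 1:G))
  # single gene at rank 1, unweighted
  top_gene <- names(stats)[order(-stats)][1]
  r <- preranked_gsea(stats, top_gene, weight_p = 0, n_perm = 100,
                      seed = 1)
  expect_equal(r$es, walk_es(stats, top_gene, 0), tolerance = 1e-12)
  expect_equal(r$es, 1)
  # random sets, weighted and unweighted
  for (p in c(0, 1)) {
    genes <- sample(names(stats), 12)
    r2 <- preranked_gsea(stats, genes, weight_p = p, n_perm = 100,
                         seed = 1)
    expect_equal(r2$es, unname(walk_es(stats, genes, p)),
                 tolerance = 1e-12)
    expect_true(abs(r2$es) <= 1)
    expect_identical(sign(r2$nes), sign(r2$es))
    expect_gte(r2$p, 1 / (r2$n_perm + 1))
  }
  expect_error(preranked_gsea(setNames(rep(1, G), names(stats)),
                              "g001", n_perm = 100), "no ranking")
})

test_that("reversing the ranking negates the unweighted ES", {
  set.seed(38)
  stats <- setNames(rnorm(80), sprintf("g%02d", 1:80))
  genes <- sample(names(stats), 8)
  es_fwd <- preranked_gsea(stats, genes, weight_p = 0, n_perm = 100,
                           seed = 1)$es
  es_rev <- preranked_gsea(-stats, genes, weight_p = 0, n_perm = 100,
                           seed = 1)$es
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
})

test_that("gene-permutation p-values are roughly uniform (small run)", {
  set.seed(39)
  G <- 200
  stats <- setNames(rnorm(G), sprintf("g%03d", 1:G))
  ps <- vapply(1:100, function(i) {
    genes <- sample(names(stats), 10)
    preranked_gsea(stats, genes, n_perm = 200, seed = i)$p
  }, 0)
  expect_lte(mean(ps < 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 1e-3)
})

test_that("pseudobulk equals the matrix-product oracle", {
  set.seed(40)
  m <- matrix(rnorm(30), 6, 5,
              dimnames = list(sprintf("c%d", 1:6), sprintf("g%d", 1:5)))
  g <- c("a", "a", "b", "b", "b", "c")
  pb <- pseudobulk(m, g)
  ind <- outer(sort(unique(g)), g, "==") * 1
  oracle <- (ind %*% m) / rowSums(ind)
  expect_equal(unname(pb[sort(unique(g)), ]), unname(oracle),
               tolerance = 1e-12)
  # single-cell group returns that cell's profile; (0,2) averages to 1
  expect_equal(unname(pb["c", ]), unname(m[6, ]))
  expect_equal(unname(pseudobulk(matrix(c(0, 2), 2, 1,
    dimnames = list(c("x", "y"), "g")), c("s", "s"))[1, 1]), 1)
})
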