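# Normalization, cluster profiles, and one-vs-rest Wilcoxon DE.

test_that("normalization follows its closed form and conserves totals", {
  cm <- count_matrix(matrix(c(10, 0, 0, 5, 5, 0), nrow = 3,
                            dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
  n <- normalize_counts(cm)
  expect_equal(n["A", "c1"], log1p(1e4)) # sole nonzero gene takes the whole scale
  expect_equal(n["B", "c1"], 0)
  # per-cell expm1 sums are conserved at the scale
  cm2 <- random_counts(100, 50, seed = 2, lambda = 3)
  n2 <- normalize_counts(cm2)
  sums <- Matrix::colSums(expm1(as.matrix(n2)))
  expect_equal(unname(sums), rep(1e4, 50), tolerance = 1e-8)
  # all-zero cell is fatal and names the barcode
  cm3 <- count_matrix(matrix(c(1, 0, 0, 0), nrow = 2,
                             dimnames = list(c("A", "B"), c("ok", "bad"))))
  expect_error(normalize_counts(cm3), "bad")
})

test_that("mean profiles equal a brute-force two-loop average", {
  cm <- random_counts(40, 30, seed = 5)
  n <- normalize_counts(cm)
  cl <- cluster_assignment(colnames(cm), rep(c("x", "y", "z"), 10))
  prof <- mean_profiles(n, cl)
  nd <- as.matrix(n)
  naive <- matrix(0, 40, 3, dimnames = list(rownames(cm), c("x", "y", "z")))
  for (g in seq_len(40)) {
    for (k in c("x", "y", "z")) {
      naive[g, k] <- mean(nd[g, names(cl)[cl == k]])
    }
  }
  expect_equal(prof, naive)
  # single cluster would be refused downstream, but the profile itself is
  # the global per-gene mean
  one <- mean_profiles(n, cluster_assignment(colnames(cm), rep("all", 30)))
  expect_equal(unname(one[, 1]), unname(rowMeans(nd)))
})

test_that("find_degs matches stats::wilcox.test per gene and cluster", {
  cm <- random_counts(25, 60, seed = 8, lambda = 1)
  n <- normalize_counts(cm)
  cl <- cluster_assignment(colnames(cm), rep(c("a", "b", "c"), each = 20))
  deg <- find_degs(n, cl, min_cells_expressing = 0)
  nd <- as.matrix(n)
  for (i in sample(nrow(deg), 30)) {
    g <- deg$gene[i]; k <- deg$cluster[i]
    x <- nd[g, names(cl)[cl == k]]
    y <- nd[g, names(cl)[cl != k]]
    if (all(c(x, y) == c(x, y)[1])) next # constant gene: handled as p = 1
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(deg$pval[i], ref, tolerance = 1e-12)
  }
})

test_that("perfectly separated genes are called with signed fold change", {
  # values fed directly on the normalized scale, to isolate the test from
  # compositional shifts of the per-cell totals
  set.seed(10)
  m <- matrix(round(runif(30 * 60), 2), 30, 60,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:60)))
  m["g01", ] <- c(seq(2, 4, length.out = 20), rep(0, 40)) # only in cluster A
  m["g02", ] <- 4 # identical everywhere
  cl <- cluster_assignment(colnames(m), rep(c("A", "B", "C"), each = 20))
  norm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  deg <- find_degs(norm, cl)
  gA <- deg[deg$gene == "g01" & deg$cluster == "A", ]
  expect_true(gA$is_significant)
  expect_gt(gA$log2_fold_change, 0)
  g2 <- deg[deg$gene == "g02", ]
  expect_false(any(g2$is_significant))
  expect_true(all(g2$pval > 0.5))
})

test_that("the normal approximation tracks the exact 6-vs-6 permutation law", {
  x <- c(8, 7, 6, 5, 4, 3)
  y <- c(2.5, 2, 1.5, 1, 0.5, 0)
  vals <- c(x, y)
  # exhaustive enumeration over all C(12,6) assignments of the in-group
  U_obs <- sum(rank(vals)[1:6]) - 6 * 7 / 2
  splits <- combn(12, 6)
  U_all <- apply(splits, 2, function(idx) sum(rank(vals)[idx]) - 6 * 7 / 2)
  mu <- 6 * 6 / 2
  p_exact <- mean(abs(U_all - mu) >= abs(U_obs - mu))
  # the same numbers through the package's vectorised path
  m <- matrix(c(vals, rep(1, 12)), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "gfill"), sprintf("c%02d", 1:12)))
  cl <- cluster_assignment(colnames(m), rep(c("in", "out"), each = 6))
  # bypass normalization: feed values directly as a sparse matrix
  norm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  deg <- find_degs(norm, cl, min_cells_expressing = 0)
  p_norm <- deg$pval[deg$gene == "g1" & deg$cluster == "in"]
  expect_equal(p_exact, 2 / choose(12, 6), tolerance = 1e-12) # both extremes
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("DE calls are invariant to cell order and monotone in alpha", {
  s <- small_sim(seed = 12, n_pops = 3, cells_per_pop = 25, n_genes = 120)
  n <- normalize_counts(s$counts)
  deg1 <- find_degs(n, s$clusters)
  set.seed(1)
  perm <- sample(ncol(n))
  deg2 <- find_degs(n[, perm], s$clusters[perm])
  o1 <- deg1[order(deg1$gene, deg1$cluster), ]
  o2 <- deg2[order(deg2$gene, deg2$cluster), ]
  expect_equal(o1$pval, o2$pval)
  expect_equal(o1$is_significant, o2$is_significant)
  # shrinking alpha never grows the DEG set
  strict <- find_degs(n, s$clusters, alpha = 0.001)
  expect_true(all(deg_genes(strict) %in% deg_genes(deg1)))
})

test_that("low-coverage genes are excluded from table and universe", {
  cm <- random_counts(20, 30, seed = 3, lambda = 0.05)
  n_expr <- Matrix::rowSums(cm > 0)
  n <- normalize_counts(cm[, Matrix::colSums(cm) > 0])
  cl <- cluster_assignment(colnames(n), rep(c("a", "b"), length.out = ncol(n)))
  deg <- find_degs(n, cl, min_cells_expressing = 3)
  expect_setequal(attr(deg, "universe"), rownames(cm)[n_expr >= 3])
  expect_true(all(deg$gene %in% attr(deg, "universe")))
})
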