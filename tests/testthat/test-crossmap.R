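# Cross-dataset cluster matching by marker-set overlap.

test_that("gene harmonization bridges symbol conventions", {
  g <- sprintf("G%03d", 1:200)
  h <- harmonize_genes(g, g, mode = "exact")
  expect_setequal(h$universe, g)
  h2 <- harmonize_genes(c("Trem2", "Cd9", rep(sprintf("Gene%03d", 1:120))),
                        c("TREM2", "CD9", toupper(sprintf("Gene%03d", 1:120))),
                        mode = "casefold")
  expect_true(all(c("TREM2", "CD9") %in% h2$universe))
  expect_length(h2$universe, 122)
  # orthology map: many-to-many rows dropped with reported count
  map <- data.frame(q = c("a", "b", "b", sprintf("q%03d", 1:120)),
                    r = c("A", "B1", "B2", sprintf("R%03d", 1:120)))
  expect_message(
    h3 <- harmonize_genes(c("a", "b", sprintf("q%03d", 1:120)),
                          c("A", "B1", sprintf("R%03d", 1:120)),
                          mode = "map_file", map = map),
    "dropped 2")
  expect_true("A" %in% h3$universe)
  expect_false(any(c("B1", "B2") %in% h3$universe))
  expect_equal(h3$n_dropped, 2L)
  # tiny shared universes are fatal, smallish ones warn
  expect_error(harmonize_genes(sprintf("x%d", 1:50), sprintf("y%d", 1:50)),
               "only")
  expect_warning(harmonize_genes(sprintf("g%d", 1:50), sprintf("g%d", 1:50)),
                 "small")
})

test_that("marker tables rank significant up-regulated genes per cluster", {
  deg <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    cluster = c("k1", "k1", "k1", "k1", "k2"),
    log2_fold_change = c(2, -3, 1, 4, 1),
    pval = c(1e-5, 1e-6, 1e-3, 1e-3, 1e-4),
    fdr = c(1e-4, 1e-5, 1e-2, 1e-2, 1e-3),
    is_significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  class(deg) <- c("deg_table", "data.frame")
  mt <- marker_table(deg, top_n = 2)
  expect_identical(mt$k1, c("a", "d")) # fdr asc, then |lfc| desc; no down, cap 2
  expect_null(mt$k2) # nothing significant in k2
  mt_all <- marker_table(deg, top_n = 10, up_only = FALSE)
  expect_identical(mt_all$k1, c("b", "a", "d", "c"))
})

test_that("matching marker sets give the minimal overlap p-value", {
  set.seed(1)
  uni <- sprintf("G%03d", 1:300)
  sig <- uni[1:40]
  q <- list(q1 = sig, q2 = uni[101:140])
  r <- list(r1 = sig, r2 = uni[201:240])
  h <- harmonize_genes(uni, uni, mode = "exact")
  res <- crossmap_clusters(q, r, h)
  calls <- res$calls
  best <- calls[which.min(calls$p_hyper), ]
  expect_equal(best$query_cluster, "q1")
  expect_equal(best$ref_cluster, "r1")
  expect_true(best$significant)
  expect_equal(best$n_overlap, 40)
  # symmetry: swapping query and reference preserves every overlap count
  res_sw <- crossmap_clusters(r, q, h)
  key <- function(d) paste(d$query_cluster, d$ref_cluster)
  m <- res_sw$calls
  for (i in seq_len(nrow(calls))) {
    j <- which(m$query_cluster == calls$ref_cluster[i] &
                 m$ref_cluster == calls$query_cluster[i])
    expect_equal(m$n_overlap[j], calls$n_overlap[i])
  }
  # shrinking top_n never increases overlap
  res_small <- crossmap_clusters(q, r, h, top_n = 10)
  expect_true(all(res_small$calls$n_overlap <= calls$n_overlap))
})

test_that("toy overlap p-value equals exhaustive enumeration", {
  uni <- sprintf("g%02d", 1:20)
  q <- list(q1 = uni[1:5])       # 5 query markers
  r <- list(r1 = uni[c(1, 2, 3, 10)]) # 4 reference markers, overlap 3
  h <- suppressWarnings(harmonize_genes(uni, uni, mode = "exact"))
  res <- crossmap_clusters(q, r, h)
  expect_equal(res$calls$n_overlap, 3)
  draws <- combn(20, 5)
  p_enum <- mean(colSums(matrix(draws %in% c(1, 2, 3, 10), nrow = 5)) >= 3)
  expect_equal(res$calls$p_hyper, p_enum, tolerance = 1e-12)
})

test_that("random marker assignment is calibrated at its exact null rate", {
  # 500-gene universe, two clusters per side with 100 markers each; the
  # expected rejection rate at raw alpha = 0.05 is computed exactly from
  # the discrete null, and the empirical rate must agree within 3 SE.
  uni <- sprintf("g%03d", 1:500)
  h <- harmonize_genes(uni, uni, mode = "exact")
  alpha <- 0.05
  # exact rate: smallest k with tail < alpha, then P(X >= k)
  tails <- vapply(0:100, function(k) hyper_tail_oracle(k, 500, 100, 100),
                  numeric(1))
  k_star <- min(which(tails < alpha)) - 1
  exact_rate <- tails[k_star + 1]
  set.seed(21)
  hits <- 0; n_pairs <- 0
  for (rep in 1:200) {
    q <- list(a = sample(uni, 100))
    r <- list(b = sample(uni, 100))
    res <- crossmap_clusters(q, r, h)
    hits <- hits + sum(res$calls$p_hyper < alpha)
    n_pairs <- n_pairs + nrow(res$calls)
  }
  se <- sqrt(exact_rate * (1 - exact_rate) / n_pairs)
  expect_lt(abs(hits / n_pairs - exact_rate), 3 * se + 0.01)
  expect_lt(abs(hits / n_pairs - alpha), 0.05) # and near the nominal level
})

test_that("clusters without usable markers yield unit p-values", {
  uni <- sprintf("g%03d", 1:200)
  h <- harmonize_genes(uni, uni, mode = "exact")
  q <- list(q1 = uni[1:10], q_empty = c("zz1", "zz2"))
  r <- list(r1 = uni[1:10])
  expect_warning(res <- crossmap_clusters(q, r, h), "no markers")
  row <- res$calls[res$calls$query_cluster == "q_empty", ]
  expect_equal(row$n_overlap, 0)
  expect_equal(row$p_hyper, 1)
})
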