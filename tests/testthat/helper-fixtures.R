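# Shared in-code fixtures; everything is generated at test time.

# tiny deterministic count matrix with named genes/barcodes
tiny_counts <- function(genes = c("A", "B", "C"), barcodes = c("c1", "c2"),
                        values = c(0, 2, 5, 1, 0, 3)) {
  count_matrix(matrix(values, nrow = length(genes),
                      dimnames = list(genes, barcodes)))
}

# random sparse count matrix
random_counts <- function(n_genes, n_cells, seed, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  count_matrix(m)
}

# small marker-block simulation shared by DE / pattern / enrichment tests
small_sim <- function(n_pops = 5, cells_per_pop = 40, n_markers = 10,
                      n_genes = 300, fold = 4, seed = 1) {
  des <- simulation_design(
    n_genes,
    make_populations(paste0("P", seq_len(n_pops)), cells_per_pop,
                     n_markers, fold, n_genes),
    seed = seed)
  simulate_counts(des)
}

# the enrichment-study design: ~600 DEGs in 10 marker blocks
study_sim <- function(seed) {
  des <- simulation_design(
    800,
    make_populations(paste0("P", 1:10), 40, 60, 4, 800),
    seed = seed)
  simulate_counts(des)
}

# run simulate -> DEG -> patterns, returning the pieces enrichment needs
study_patterns <- function(seed, K = 10, n_restarts = 10) {
  s <- study_sim(seed)
  norm <- normalize_counts(s$counts)
  deg <- suppressWarnings(find_degs(norm, s$clusters))
  ds <- deg_genes(deg)
  z <- zscore_profiles(mean_profiles(norm, s$clusters), ds)
  ps <- annotate_patterns(build_patterns(z, K = K, n_restarts = n_restarts,
                                         seed = seed + 1000L))
  list(sim = s, deg = deg, deg_set = ds, universe = attr(deg, "universe"),
       patterns = ps)
}

# adjusted Rand index between two partitions (independent small helper)
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# exact upper-tail overlap probability by combinatorial sum (oracle,
# independent of stats::phyper)
hyper_tail_oracle <- function(observed, N, m, k) {
  j <- observed:min(m, k)
  sum(choose(m, j) * choose(N - m, k - j)) / choose(N, k)
}
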