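# Permutation enrichment and its exact hypergeometric twin.

test_that("degenerate overlap cases behave as contracts demand", {
  universe <- sprintf("g%03d", 1:40)
  deg <- universe[1:10]
  # candidates disjoint from the DEG set
  r <- global_overlap_test(universe[31:35], deg, universe, n_perm = 500, seed = 1)
  expect_equal(r$n_observed_overlap, 0)
  expect_equal(r$p_perm, 1)
  expect_equal(r$p_hyper, 1)
  # universe equal to the DEG set: every draw overlaps fully
  r2 <- global_overlap_test(deg[1:5], deg, deg, n_perm = 500, seed = 1)
  expect_equal(r2$p_perm, 1)
  expect_equal(r2$n_observed_overlap, 5)
  # candidates entirely outside the universe are fatal with diagnostics
  expect_error(global_overlap_test(c("nope1", "nope2"), deg, universe),
               "nope1")
})

test_that("hypergeometric tail equals true exhaustive enumeration", {
  # universe 20, DEG set 8, candidates 5, observed 4
  universe <- sprintf("g%02d", 1:20)
  deg <- universe[1:8]
  cand <- c(universe[1:4], universe[20])
  r <- global_overlap_test(cand, deg, universe, n_perm = 20000, seed = 3)
  expect_equal(r$n_observed_overlap, 4)
  # full enumeration over all C(20,5) candidate draws
  draws <- combn(20, 5)
  p_enum <- mean(colSums(matrix(draws %in% 1:8, nrow = 5)) >= 4)
  expect_equal(r$p_hyper, p_enum, tolerance = 1e-12)
  se <- sqrt(p_enum * (1 - p_enum) / 20000)
  expect_lt(abs(r$p_perm - p_enum), 3 * se + 1e-12)
})

mk_patterns <- function(assignments) {
  structure(list(K = max(assignments), assignments = assignments,
                 centroids = NULL,
                 sizes = tabulate(assignments, max(assignments)),
                 annotations = NULL),
            class = "pattern_set")
}

test_that("per-pattern accumulation matches combinatorial tails", {
  # DEG set of 60 in 3 patterns of 20; |S| = 9 observed as (6, 2, 1)
  deg <- sprintf("d%02d", 1:60)
  pat <- mk_patterns(setNames(rep(1:3, each = 20), deg))
  S <- c(deg[1:6], deg[21:22], deg[41])
  r <- pattern_accumulation_test(S, pat, deg, n_perm = 20000, seed = 5)
  expect_equal(r$n_observed_overlap, c(6, 2, 1))
  for (k in 1:3) {
    p_oracle <- hyper_tail_oracle(r$n_observed_overlap[k], 60, 20, 9)
    expect_equal(r$p_hyper[k], p_oracle, tolerance = 1e-12)
    se <- sqrt(p_oracle * (1 - p_oracle) / 20000)
    expect_lt(abs(r$p_perm[k] - p_oracle), 3 * se + 1e-12)
  }
  # S concentrated in one small pattern attains the floor p
  pat2 <- mk_patterns(setNames(c(rep(1, 5), rep(2, 55)), deg))
  r2 <- pattern_accumulation_test(deg[1:5], pat2, deg, n_perm = 2000, seed = 2)
  expect_equal(r2$p_perm[1], 1 / 2001)
  # proportionally spread candidates show no enrichment anywhere
  S3 <- c(deg[1:3], deg[21:23], deg[41:43])
  r3 <- pattern_accumulation_test(S3, pat, deg, n_perm = 4000, seed = 7)
  expect_true(all(abs(r3$fold_enrichment - 1) < 0.35))
  expect_true(all(r3$p_perm > 0.05))
  # empty overlap with the DEG set is fatal
  expect_error(pattern_accumulation_test("zz", pat, deg), "global test")
})

test_that("permutation p-values are seeded and reproducible", {
  universe <- sprintf("g%03d", 1:100)
  deg <- universe[1:30]
  cand <- universe[seq(1, 99, by = 7)]
  a <- global_overlap_test(cand, deg, universe, n_perm = 3000, seed = 11)
  b <- global_overlap_test(cand, deg, universe, n_perm = 3000, seed = 11)
  expect_identical(a$p_perm, b$p_perm)
  c_ <- global_overlap_test(cand, deg, universe, n_perm = 3000, seed = 12)
  expect_false(identical(a$p_perm, c_$p_perm) && identical(a$expected_overlap, c_$expected_overlap))
  # p floor: (b+1)/(n+1) can never reach zero
  expect_gte(a$p_perm, 1 / 3001)
})

test_that("summaries adjust p-values exactly as BH prescribes", {
  mk <- function(p, scope) {
    r <- global_overlap_test(sprintf("g%03d", 1:5), sprintf("g%03d", 1:10),
                             sprintf("g%03d", 1:40), n_perm = 100, seed = 1)
    r$p_perm <- p; r$scope <- scope
    r
  }
  one <- summarize_enrichment(mk(0.04, "global"))
  expect_equal(one$q_value, 0.04)
  three <- summarize_enrichment(lapply(1:3, function(i)
    mk(c(0.01, 0.02, 0.03)[i], paste("pattern", i))))
  expect_equal(three$q_value, rep(0.03, 3))
  # random p-vectors against an independent step-up implementation
  set.seed(13)
  for (rep in 1:5) {
    p <- runif(8)
    res <- summarize_enrichment(lapply(seq_along(p), function(i)
      mk(p[i], paste("pattern", i))))
    o <- order(p)
    q <- p[o] * 8 / seq_len(8)
    q <- rev(cummin(rev(q)))
    q_brute <- numeric(8); q_brute[o] <- pmin(q, 1)
    expect_equal(res$q_value, q_brute[order(p)], tolerance = 1e-12)
  }
})
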