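## Candidate-gene enrichment: permutation test over random gene sets of
## matched size, always co-reported with its analytic twin, the exact
## hypergeometric upper tail. One-sided (enrichment) throughout; the
## empirical p-value uses the (b+1)/(n+1) estimator so p = 0 is impossible.

new_enrichment_result <- function(scope, n_universe, n_candidates, n_target,
                                  observed, expected, p_perm, p_hyper,
                                  n_perm, seed) {
  structure(data.frame(scope = scope, n_universe = n_universe,
                       n_candidates_in_universe = n_candidates,
                       n_target_set = n_target,
                       n_observed_overlap = observed,
                       expected_overlap = expected,
                       fold_enrichment = ifelse(expected > 0,
                                                observed / expected, NA_real_),
                       p_perm = p_perm, p_hyper = p_hyper,
                       n_perm = n_perm, seed = seed,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Global overlap of candidate genes with the DEG set
#'
#' Observed statistic: `|candidates ∩ deg_set|` after intersecting the
#' candidates with the gene universe (dropped symbols are reported). Null:
#' `n_perm` uniform draws of the same number of genes without replacement
#' from the universe; `p_perm = (1 + #{draws >= observed}) / (n_perm + 1)`.
#' The exact hypergeometric upper tail `P(X >= observed)` (population
#' = universe, successes = DEG set, draws = candidates in universe) is
#' co-reported as `p_hyper`.
#'
#' @param candidates Character vector of candidate genes.
#' @param deg_set Character vector, the DEG set (must lie in `universe`).
#' @param universe Character vector, the gene universe the null samples from.
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @return A one-row `enrichment_result` (also a `data.frame`).
#' @export
global_overlap_test <- function(candidates, deg_set, universe,
                                n_perm = 10000, seed = 1L) {
  candidates <- unique(candidates)
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% universe)) pm_stop("deg_set must be a subset of the universe")
  in_univ <- candidates %in% universe
  if (!all(in_univ)) {
    message("global_overlap_test: ", sum(!in_univ),
            " candidate(s) outside the universe dropped")
  }
  cand <- candidates[in_univ]
  if (length(cand) == 0) {
    pm_stop("no candidate overlaps the universe; first unmatched symbols: ",
            paste(utils::head(candidates, 10), collapse = ", "))
  }
  observed <- length(intersect(cand, deg_set))
  N <- length(universe); m <- length(deg_set); k <- length(cand)
  is_deg <- universe %in% deg_set
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(is_deg[sample.int(N, k)]), numeric(1))
  })
  p_perm <- (1 + sum(draws >= observed)) / (n_perm + 1)
  p_hyper <- stats::phyper(observed - 1, m, N - m, k, lower.tail = FALSE)
  new_enrichment_result("global", N, k, m, observed, mean(draws),
                        p_perm, p_hyper, n_perm, seed)
}

#' Per-pattern accumulation of candidate genes
#'
#' Restricts the candidates to the DEG set (`S = candidates ∩ deg_set`) and
#' asks, for each expression pattern, whether S accumulates in it. Null:
#' `n_perm` uniform draws of `|S|` genes without replacement from the DEG
#' set, counted per pattern through the fixed assignment map; one shared
#' permutation stream serves every pattern, so per-pattern p-values are
#' reproducible and mutually consistent. The hypergeometric twin uses
#' population `|deg_set|`, successes `|pattern_k|`, draws `|S|`.
#'
#' @param candidates Character vector of candidate genes.
#' @param patterns A `pattern_set` whose assignments cover `deg_set`.
#' @param deg_set Character vector, the DEG set.
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @return An `enrichment_result` with one row per pattern
#'   (`scope = "pattern k"`).
#' @export
pattern_accumulation_test <- function(candidates, patterns, deg_set,
                                      n_perm = 10000, seed = 1L) {
  stopifnot(inherits(patterns, "pattern_set"))
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% names(patterns$assignments))) {
    pm_stop("pattern assignments must cover the DEG set")
  }
  S <- intersect(unique(candidates), deg_set)
  if (length(S) == 0) {
    pm_stop("no candidate gene lies in the DEG set; run the global test first")
  }
  K <- patterns$K
  pat_of <- patterns$assignments[deg_set]
  observed <- tabulate(pat_of[S], K)
  n_deg <- length(deg_set); s <- length(S)
  pat_vec <- unname(pat_of)
  counts <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) tabulate(pat_vec[sample.int(n_deg, s)], K),
           numeric(K))
  })
  if (K == 1) counts <- matrix(counts, nrow = 1)
  exceed <- rowSums(counts >= observed)
  p_perm <- (1 + exceed) / (n_perm + 1)
  expected <- rowMeans(counts)
  m_k <- tabulate(pat_vec, K)
  p_hyper <- stats::phyper(observed - 1, m_k, n_deg - m_k, s, lower.tail = FALSE)
  new_enrichment_result(paste("pattern", seq_len(K)), n_deg, s, m_k,
                        observed, expected, p_perm, p_hyper, n_perm, seed)
}

#' Summarize enrichment results with optional BH adjustment
#'
#' Orders results by permutation p-value (ties by original order), and adds
#' BH-adjusted q-values with a significance flag at `q < alpha`. Raw
#' permutation p-values remain the primary output; the adjustment is an
#' optional, clearly flagged extra.
#'
#' @param results One or more `enrichment_result` objects (rows are
#'   concatenated).
#' @param fdr_method Adjustment method (only `"BH"` supported).
#' @param alpha Significance threshold on q (default 0.05).
#' @return `data.frame` of the input rows plus `q_value` and `significant`,
#'   ordered by `p_perm`.
#' @export
summarize_enrichment <- function(results, fdr_method = "BH", alpha = 0.05) {
  if (inherits(results, "data.frame")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  if (nrow(df) == 0) pm_stop("no enrichment results to summarize")
  stopifnot(fdr_method == "BH")
  df$q_value <- bh_adjust(df$p_perm)
  df$significant <- df$q_value < alpha
  df <- df[order(df$p_perm, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat("Gene-set enrichment (permutation + hypergeometric)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-10s overlap %d/%d (expected %.2f, fold %.2f)  p_perm=%.3g  p_hyper=%.3g\n",
      x$scope[i], x$n_observed_overlap[i], x$n_candidates_in_universe[i],
      x$expected_overlap[i], x$fold_enrichment[i], x$p_perm[i], x$p_hyper[i]))
  }
  invisible(x)
}
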