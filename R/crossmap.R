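## Cross-dataset cluster correspondence: harmonize gene symbols between two
## datasets (e.g., mouse and human), build per-cluster marker signatures,
## and test every query x reference cluster pair for marker overlap with an
## upper-tail hypergeometric test, BH-adjusted over all pairs.

#' Harmonize gene symbols between two datasets
#'
#' `exact` intersects the symbol lists as-is; `casefold` uppercases both
#' sides first (the usual human/mouse symbol-convention bridge, Trem2 vs
#' TREM2); `map_file` applies a two-column orthology table (query symbol,
#' reference symbol), dropping many-to-many rows with a reported count.
#'
#' @param query_genes,ref_genes Character vectors of gene symbols.
#' @param mode One of `"exact"`, `"casefold"`, `"map_file"`.
#' @param map For `map_file`: a `data.frame` (or path to a two-column TSV,
#'   no header) mapping query to reference symbols.
#' @return List with `universe` (shared symbols, in harmonized space),
#'   `query_map` and `ref_map` (named character vectors original ->
#'   harmonized), and `n_dropped` (many-to-many orthology rows removed).
#' @export
harmonize_genes <- function(query_genes, ref_genes,
                            mode = c("casefold", "exact", "map_file"),
                            map = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(query_genes) > 0, length(ref_genes) > 0)
  n_dropped <- 0L
  if (mode == "exact") {
    qm <- stats::setNames(query_genes, query_genes)
    rm_ <- stats::setNames(ref_genes, ref_genes)
  } else if (mode == "casefold") {
    qm <- stats::setNames(toupper(query_genes), query_genes)
    rm_ <- stats::setNames(toupper(ref_genes), ref_genes)
  } else {
    if (is.character(map)) {
      map <- utils::read.delim(map, header = FALSE, stringsAsFactors = FALSE)
    }
    if (is.null(map) || ncol(map) < 2) pm_stop("map_file mode needs a two-column orthology table")
    dup <- duplicated(map[[1]]) | duplicated(map[[1]], fromLast = TRUE) |
      duplicated(map[[2]]) | duplicated(map[[2]], fromLast = TRUE)
    n_dropped <- sum(dup)
    if (n_dropped > 0) {
      message("harmonize_genes: dropped ", n_dropped, " many-to-many orthology row(s)")
      map <- map[!dup, , drop = FALSE]
    }
    qm <- stats::setNames(map[[2]], map[[1]])[query_genes]
    names(qm) <- query_genes
    qm <- qm[!is.na(qm)]
    rm_ <- stats::setNames(ref_genes, ref_genes)
  }
  universe <- intersect(unname(qm), unname(rm_))
  if (length(universe) < 10) {
    pm_stop("shared gene universe has only ", length(universe), " genes")
  }
  if (length(universe) < 100) {
    warning("shared gene universe is small (", length(universe), " genes)")
  }
  list(universe = universe, query_map = qm, ref_map = rm_,
       n_dropped = n_dropped)
}

#' Build per-cluster marker signatures from a DEG table
#'
#' For each cluster, significant up-regulated genes ordered by ascending
#' FDR, ties by descending |log2 fold change|, capped at `top_n`.
#'
#' @param deg A `deg_table` from [find_degs()].
#' @param top_n Maximum markers per cluster (default 100).
#' @param up_only Keep only positively enriched markers (default TRUE).
#' @return Named list: cluster -> character vector of marker genes.
#' @export
marker_table <- function(deg, top_n = 100, up_only = TRUE) {
  d <- deg[deg$is_significant & (!up_only | deg$log2_fold_change > 0), ,
           drop = FALSE]
  out <- lapply(split(d, d$cluster), function(g) {
    g <- g[order(g$fdr, -abs(g$log2_fold_change)), , drop = FALSE]
    utils::head(unique(g$gene), top_n)
  })
  out[order(names(out))]
}

#' Test all query x reference cluster pairs for marker overlap
#'
#' Marker lists are first renamed into the harmonized symbol space and
#' restricted to the shared universe, then capped at `top_n`. For each pair,
#' the upper-tail hypergeometric p-value of the observed marker overlap is
#' computed (population = shared universe, successes = reference markers,
#' draws = query markers), BH-adjusted over all pairs jointly; a pair is a
#' significant correspondence at `q < alpha`.
#'
#' @param query,ref Marker tables ([marker_table()] output), in each
#'   dataset's own symbol space.
#' @param harmonized Output of [harmonize_genes()] for the two gene spaces.
#' @param top_n Marker cap per cluster after universe restriction.
#' @param alpha Significance threshold on BH q-values (default 0.05).
#' @return List with `calls` (`data.frame`: query_cluster, ref_cluster,
#'   n_shared_universe, n_query_markers, n_ref_markers, n_overlap, p_hyper,
#'   q_bh, significant) and `top5` (per query cluster, the top-5 reference
#'   clusters by overlap count).
#' @export
crossmap_clusters <- function(query, ref, harmonized, top_n = 100,
                              alpha = 0.05) {
  universe <- harmonized$universe
  restrict <- function(markers, map) {
    m <- unname(map[markers])
    m <- m[!is.na(m) & m %in% universe]
    utils::head(unique(m), top_n)
  }
  q_sets <- lapply(query, restrict, map = harmonized$query_map)
  r_sets <- lapply(ref, restrict, map = harmonized$ref_map)
  empty <- c(names(q_sets)[lengths(q_sets) == 0], names(r_sets)[lengths(r_sets) == 0])
  if (length(empty) > 0) {
    warning("cluster(s) with no markers in the shared universe: ",
            paste(unique(empty), collapse = ", "))
  }
  N <- length(universe)
  grid <- expand.grid(query_cluster = names(q_sets), ref_cluster = names(r_sets),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    qs <- q_sets[[grid$query_cluster[i]]]
    rs <- r_sets[[grid$ref_cluster[i]]]
    ov <- length(intersect(qs, rs))
    p <- if (length(qs) == 0 || length(rs) == 0) 1 else
      stats::phyper(ov - 1, length(rs), N - length(rs), length(qs),
                    lower.tail = FALSE)
    data.frame(query_cluster = grid$query_cluster[i],
               ref_cluster = grid$ref_cluster[i],
               n_shared_universe = N,
               n_query_markers = length(qs), n_ref_markers = length(rs),
               n_overlap = ov, p_hyper = p, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, res)
  calls$q_bh <- bh_adjust(calls$p_hyper)
  calls$significant <- calls$q_bh < alpha
  top5 <- do.call(rbind, lapply(split(calls, calls$query_cluster), function(g) {
    g <- g[order(-g$n_overlap, g$p_hyper), , drop = FALSE]
    utils::head(g, 5)
  }))
  rownames(calls) <- rownames(top5) <- NULL
  list(calls = calls, top5 = top5)
}
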