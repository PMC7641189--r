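## Expression workup: library-size normalization, per-cluster mean profiles,
## and one-vs-rest Wilcoxon differential expression across clusters.

#' Library-size normalize a count matrix (CP10K log1p)
#'
#' `value(g, c) = log1p(count(g, c) / total(c) * scale)`: counts per cell
#' scaled to a common total (default 1e4), then log(1 + x). Zeros map to
#' zeros, so sparsity is preserved.
#'
#' @param counts Validated count matrix (genes x cells).
#' @param scale Per-cell target total (default `1e4`).
#' @return Sparse normalized matrix with the same dimnames.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    pm_stop("cells with zero total count: ",
            paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  }
  norm <- counts %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

#' Per-cluster mean expression profiles
#'
#' Column `j` of the result is the arithmetic mean of the normalized values
#' over the cells of cluster `j`. Cells without a cluster label are ignored;
#' clusters that end up with zero cells are dropped with a warning.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param clusters Named factor mapping barcode to cluster label.
#' @return Dense genes x clusters matrix of means.
#' @export
mean_profiles <- function(norm, clusters) {
  clusters <- clusters[names(clusters) %in% colnames(norm)]
  clusters <- droplevels(clusters)
  empty <- !(levels(clusters) %in% unique(as.character(clusters)))
  if (any(empty)) {
    warning("dropping empty cluster(s): ",
            paste(levels(clusters)[empty], collapse = ", "))
    clusters <- droplevels(clusters)
  }
  labs <- levels(clusters)
  ind <- Matrix::sparseMatrix(
    i = match(names(clusters), colnames(norm)),
    j = as.integer(clusters),
    x = 1, dims = c(ncol(norm), length(labs)))
  sizes <- table(clusters)[labs]
  prof <- as.matrix(norm %*% ind %*% Matrix::Diagonal(x = 1 / as.numeric(sizes)))
  dimnames(prof) <- list(rownames(norm), labs)
  prof
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For every (gene, cluster) pair, tests the gene's normalized values in the
#' cluster against all other cells with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie and continuity correction), computed
#' vectorised from a single per-gene ranking. P-values are BH-adjusted over
#' the whole (gene, cluster) table; a pair is significant when
#' `fdr < alpha` and `|log2_fold_change| >= lfc_min`. Log2 fold changes are
#' computed on `expm1`-scale cluster means with a small pseudocount.
#'
#' Genes expressed (count > 0) in fewer than `min_cells_expressing` cells
#' are excluded from testing and from the reported gene universe; clusters
#' with fewer than 3 cells are skipped with a warning.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param clusters Named factor of cluster labels.
#' @param alpha FDR threshold for significance (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 0.25).
#' @param min_cells_expressing Minimum cells with nonzero counts for a gene
#'   to enter the analysis (default 3).
#' @return A `deg_table`: `data.frame` with columns gene, cluster,
#'   log2_fold_change, pval, fdr, is_significant; attribute `universe`
#'   holds the tested gene universe.
#' @seealso [deg_genes()] for the union DEG set.
#' @export
find_degs <- function(norm, clusters, alpha = 0.05, lfc_min = 0.25,
                      min_cells_expressing = 3) {
  clusters <- droplevels(clusters[names(clusters) %in% colnames(norm)])
  if (nlevels(clusters) < 2) pm_stop("need >=2 clusters for differential expression")
  X <- norm[, names(clusters), drop = FALSE]
  n_expr <- Matrix::rowSums(X > 0)
  keep <- n_expr >= min_cells_expressing
  universe <- rownames(X)[keep]
  X <- X[keep, , drop = FALSE]
  Xd <- as.matrix(X)
  G <- nrow(Xd); n <- ncol(Xd)

  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warning("skipping cluster(s) with <3 cells: ", paste(small, collapse = ", "))
  }
  labs <- setdiff(levels(clusters), small)
  if (length(labs) < 1) pm_stop("no cluster with >=3 cells")

  # one ranking per gene serves every one-vs-rest contrast
  R <- matrix(0, G, n)
  tie_term <- numeric(G)
  for (g in seq_len(G)) {
    x <- Xd[g, ]
    R[g, ] <- rank(x)
    t <- rle(sort(x))$lengths
    tie_term[g] <- sum(t^3 - t)
  }

  Ed <- as.matrix(expm1(X)) # CP10K scale for fold changes
  eps <- 1e-9
  res <- vector("list", length(labs))
  for (j in seq_along(labs)) {
    in_cl <- as.character(clusters) == labs[j]
    n1 <- sum(in_cl); n2 <- n - n1
    rank_sum <- R[, in_cl, drop = FALSE] %*% rep(1, n1)
    U <- as.numeric(rank_sum) - n1 * (n1 + 1) / 2
    mu_U <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    d <- U - mu_U
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p[sigma2 <= 0] <- 1
    p <- pmin(p, 1)
    m1 <- Ed[, in_cl, drop = FALSE] %*% rep(1 / n1, n1)
    m2 <- Ed[, !in_cl, drop = FALSE] %*% rep(1 / n2, n2)
    res[[j]] <- data.frame(gene = rownames(Xd), cluster = labs[j],
                           log2_fold_change = log2((as.numeric(m1) + eps) /
                                                     (as.numeric(m2) + eps)),
                           pval = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$pval)
  out$is_significant <- out$fdr < alpha & abs(out$log2_fold_change) >= lfc_min
  rownames(out) <- NULL
  attr(out, "universe") <- universe
  class(out) <- c("deg_table", "data.frame")
  out
}

#' The union DEG set of a differential-expression table
#'
#' Genes significant in at least one cluster.
#'
#' @param deg A `deg_table` from [find_degs()].
#' @return Character vector of gene symbols (in gene-universe order).
#' @export
deg_genes <- function(deg) {
  g <- unique(deg$gene[deg$is_significant])
  u <- attr(deg, "universe")
  if (!is.null(u)) g <- u[u %in% g]
  g
}

#' @exportS3Method base::print
print.deg_table <- function(x, ...) {
  cat("Differential expression (one-vs-rest Wilcoxon)\n")
  cat("  tested pairs : ", nrow(x), "\n", sep = "")
  cat("  gene universe: ", length(attr(x, "universe")), "\n", sep = "")
  cat("  DEG set      : ", length(unique(x$gene[x$is_significant])),
      " genes significant in >=1 cluster\n", sep = "")
  invisible(x)
}

#' Write / read a differential-expression table
#' @param deg A `deg_table`.
#' @param path Output TSV path.
#' @export
write_deg_table <- function(deg, path) {
  write_tsv(as.data.frame(deg), path)
}

#' @rdname write_deg_table
#' @param universe Optional gene universe to attach on read.
#' @export
read_deg_table <- function(path, universe = NULL) {
  df <- read_tsv(path)
  df$is_significant <- as.logical(df$is_significant)
  attr(df, "universe") <- universe
  class(df) <- c("deg_table", "data.frame")
  df
}
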