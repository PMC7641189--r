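## Grouping DEGs into expression patterns: z-scored per-cluster mean
## profiles, deterministic k-means (k-means++ / Lloyd, seeded restarts),
## and annotation of each pattern with the populations it represents.

#' Z-score per-cluster mean profiles of the DEG set
#'
#' Each gene's row of cluster means is centered and scaled to unit variance
#' across clusters (population standard deviation), so genes of different
#' expression magnitude become comparable relative profiles. Rows with zero
#' variance get a zero vector and a warning.
#'
#' @param profile Genes x clusters matrix from [mean_profiles()].
#' @param deg_genes Genes to keep (typically [deg_genes()] of a DEG table).
#' @return Z-scored genes x clusters matrix restricted to `deg_genes`.
#' @export
zscore_profiles <- function(profile, deg_genes = rownames(profile)) {
  missing <- setdiff(deg_genes, rownames(profile))
  if (length(missing) > 0) pm_stop("genes absent from profile: ",
                                   paste(utils::head(missing, 5), collapse = ", "))
  m <- profile[deg_genes, , drop = FALSE]
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  zero <- sd_pop == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance profile row(s) set to z = 0")
    sd_pop[zero] <- 1
  }
  z <- centered / sd_pop
  z[zero, ] <- 0
  z
}

# k-means++ initial centers (indices into rows of x)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

# Lloyd iterations with empty-cluster reseeding from the farthest point.
# Ties in assignment go to the lowest cluster index (which.min convention).
lloyd <- function(x, centers, iter_max = 100) {
  n <- nrow(x); k <- nrow(centers)
  xsq <- rowSums(x^2)
  assign_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    # squared distances: ||x||^2 - 2 x.c + ||c||^2
    d <- outer(xsq, rowSums(centers^2), `+`) - 2 * x %*% t(centers)
    assign <- max.col(-d, ties.method = "first")
    # reseed empty clusters from the farthest point
    repeat {
      sizes <- tabulate(assign, k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      dmin <- d[cbind(seq_len(n), assign)]
      far <- which.max(dmin)
      assign[far] <- empty[1]
      centers[empty[1], ] <- x[far, ]
      d[, empty[1]] <- rowSums((x - matrix(x[far, ], n, ncol(x), byrow = TRUE))^2)
    }
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    }
  }
  d <- outer(xsq, rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  wss <- sum(pmax(d[cbind(seq_len(n), assign)], 0))
  list(assign = assign, centers = centers, wss = wss)
}

#' Group z-scored profiles into K expression patterns
#'
#' K-means with Lloyd iterations and k-means++ initialization, run
#' `n_restarts` times from a seeded generator; the solution with minimum
#' within-cluster sum of squares is kept (first winner on ties). Empty
#' clusters are re-seeded from the point farthest from its center. Patterns
#' are re-indexed by descending member count (ties by smallest original
#' index), so pattern 1 is always the largest. Deterministic given `seed`.
#'
#' @param z_profiles Genes x clusters z-score matrix from
#'   [zscore_profiles()].
#' @param K Number of patterns (default 15).
#' @param n_restarts Independent k-means++ restarts (default 50).
#' @param seed Integer seed.
#' @return A `pattern_set`: list with `K`, `assignments` (named integer
#'   vector gene -> pattern), `centroids` (K x clusters matrix of mean
#'   member z-profiles), `sizes`, and `wss`.
#' @export
build_patterns <- function(z_profiles, K = 15, n_restarts = 50, seed = 1L) {
  if (K < 2) pm_stop("K must be >= 2")
  x <- as.matrix(z_profiles)
  if (nrow(x) < K) pm_stop("fewer genes (", nrow(x), ") than patterns (", K, ")")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- x[kmeanspp_init(x, K), , drop = FALSE]
      fit <- lloyd(x, init)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  # re-index by descending size, ties by smallest original index
  sizes <- tabulate(best$assign, K)
  ord <- order(-sizes, seq_len(K))
  remap <- integer(K); remap[ord] <- seq_len(K)
  assign <- remap[best$assign]
  names(assign) <- rownames(x)
  centroids <- matrix(0, K, ncol(x), dimnames = list(NULL, colnames(x)))
  for (j in seq_len(K)) {
    centroids[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  structure(list(K = K, assignments = assign, centroids = centroids,
                 sizes = tabulate(assign, K), wss = best$wss,
                 annotations = NULL),
            class = "pattern_set")
}

#' Annotate patterns with the populations they represent
#'
#' A pattern is annotated with every population whose centroid z-score is at
#' least `z_annot`; if none reaches it, the argmax population is used as a
#' single-label fallback.
#'
#' @param patterns A `pattern_set` from [build_patterns()].
#' @param z_annot Annotation threshold on the centroid z-score (default 1).
#' @return The `pattern_set` with an `annotations` list (one character
#'   vector of population labels per pattern).
#' @export
annotate_patterns <- function(patterns, z_annot = 1.0) {
  stopifnot(inherits(patterns, "pattern_set"))
  labs <- colnames(patterns$centroids)
  patterns$annotations <- lapply(seq_len(patterns$K), function(j) {
    z <- patterns$centroids[j, ]
    hit <- labs[z >= z_annot]
    if (length(hit) == 0) labs[which.max(z)] else hit
  })
  patterns$z_annot <- z_annot
  patterns
}

#' @exportS3Method base::print
print.pattern_set <- function(x, ...) {
  cat("Expression patterns: K = ", x$K, ", ", length(x$assignments),
      " genes\n", sep = "")
  for (j in seq_len(x$K)) {
    ann <- if (is.null(x$annotations)) "" else
      paste0("  [", paste(x$annotations[[j]], collapse = ", "), "]")
    cat(sprintf("  pattern %2d: %4d genes%s\n", j, x$sizes[j], ann))
  }
  invisible(x)
}

#' Write pattern membership and centroids as TSV
#' @param patterns A `pattern_set`.
#' @param path_members,path_centroids Output paths.
#' @export
write_patterns <- function(patterns, path_members, path_centroids) {
  ann <- if (is.null(patterns$annotations)) rep("", patterns$K) else
    vapply(patterns$annotations, paste, character(1), collapse = ",")
  write_tsv(data.frame(gene = names(patterns$assignments),
                       pattern = unname(patterns$assignments),
                       stringsAsFactors = FALSE), path_members)
  cent <- data.frame(pattern = seq_len(patterns$K),
                     n_genes = patterns$sizes,
                     annotation = ann,
                     patterns$centroids, check.names = FALSE)
  write_tsv(cent, path_centroids)
  invisible(NULL)
}
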