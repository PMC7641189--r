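## Synthetic data with planted structure: negative-binomial counts with
## population-specific markers, a mixed low-identity population, GWAS
## summary-statistic fixtures with variants planted in chosen genes, and
## candidate gene sets enriched for a target population's markers.

#' Specify a single-cell count simulation
#'
#' Describes a plaque-like dataset: discrete cell populations of unequal
#' size, each with a disjoint set of marker genes elevated by a fold factor
#' over a shared log-normal baseline, negative-binomial counting noise,
#' log-normal library-size variation, and optionally a fraction of "mixed"
#' cells drawn as 50/50 mixtures of two random populations (emulating a
#' low-identity cluster of apoptotic-like cells).
#'
#' @param n_genes Number of genes (named `g0001`, `g0002`, ...).
#' @param populations List of population specs, each a list with `label`,
#'   `n_cells`, `markers` (character vector of gene names) and `marker_fold`
#'   (> 1). Marker sets must be disjoint across populations. See
#'   [make_populations()].
#' @param baseline_mean_logmu,baseline_mean_logsigma Log-normal parameters
#'   of the per-gene baseline mean expression.
#' @param dispersion Negative-binomial dispersion phi, with
#'   `variance = mu + phi * mu^2`.
#' @param libsize_logsigma Log-normal sigma of per-cell library-size factors
#'   (mean factor 1 on the log scale).
#' @param mixed_fraction Fraction of all cells that are mixtures of two
#'   random populations, in \[0, 1).
#' @param mixed_assign `"mixed"` labels mixture cells as a separate `Mixed`
#'   cluster (default); `"dominant"` assigns them to their first parent.
#' @param seed Integer seed; the simulation is a pure function of the design.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes, populations,
                              baseline_mean_logmu = -1,
                              baseline_mean_logsigma = 1,
                              dispersion = 0.5,
                              libsize_logsigma = 0.35,
                              mixed_fraction = 0,
                              mixed_assign = c("mixed", "dominant"),
                              seed = 1L) {
  mixed_assign <- match.arg(mixed_assign)
  stopifnot(n_genes >= 1, dispersion > 0, libsize_logsigma >= 0,
            mixed_fraction >= 0, mixed_fraction < 1,
            length(populations) >= 1)
  genes <- sprintf("g%04d", seq_len(n_genes))
  all_markers <- character(0)
  for (p in populations) {
    stopifnot(!is.null(p$label), !is.null(p$n_cells), !is.null(p$marker_fold))
    if (p$n_cells < 2) pm_validation_error("population '", p$label, "' needs >= 2 cells")
    if (p$marker_fold <= 1) pm_validation_error("marker_fold must be > 1")
    if (!all(p$markers %in% genes)) {
      pm_stop("population '", p$label, "' references genes outside 1..n_genes")
    }
    if (any(p$markers %in% all_markers)) {
      pm_validation_error("marker gene lists must be disjoint across populations")
    }
    all_markers <- c(all_markers, p$markers)
  }
  structure(list(n_genes = n_genes, genes = genes, populations = populations,
                 baseline_mean_logmu = baseline_mean_logmu,
                 baseline_mean_logsigma = baseline_mean_logsigma,
                 dispersion = dispersion,
                 libsize_logsigma = libsize_logsigma,
                 mixed_fraction = mixed_fraction,
                 mixed_assign = mixed_assign,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Build equally specified populations with disjoint marker blocks
#'
#' Convenience constructor: population `i` gets `n_markers` consecutive
#' genes starting at gene `(i-1) * n_markers + 1` as markers.
#'
#' @param labels Character vector of population labels.
#' @param n_cells Integer vector (recycled) of cells per population.
#' @param n_markers Markers per population.
#' @param marker_fold Fold elevation of markers in their population.
#' @param n_genes Total genes in the design (must fit all marker blocks).
#' @return List of population specs for [simulation_design()].
#' @export
make_populations <- function(labels, n_cells, n_markers, marker_fold, n_genes) {
  k <- length(labels)
  n_cells <- rep_len(n_cells, k)
  if (k * n_markers > n_genes) pm_stop("marker blocks exceed n_genes")
  genes <- sprintf("g%04d", seq_len(n_genes))
  lapply(seq_len(k), function(i) {
    list(label = labels[i], n_cells = n_cells[i],
         markers = genes[((i - 1) * n_markers + 1):(i * n_markers)],
         marker_fold = marker_fold)
  })
}

#' The bundled 14-population plaque preset
#'
#' Approximates the composition of an atherosclerotic-plaque single-cell
#' atlas: 3282 cells in 14 populations, T-cell clusters totalling ~52.4% of
#' cells, a myeloid block of ~18.5%, smooth-muscle and two endothelial
#' clusters, a B-cell cluster, and ~10% mixed low-identity cells as their
#' own `Mixed` cluster.
#'
#' @param n_cells Total number of cells (default 3282).
#' @param n_genes Number of genes (default 2000).
#' @param n_markers Markers per population (default 15).
#' @param marker_fold Marker fold elevation (default 4).
#' @param seed Seed passed to [simulation_design()].
#' @return A `simulation_design`.
#' @export
plaque_preset <- function(n_cells = 3282, n_genes = 2000, n_markers = 15,
                          marker_fold = 4, seed = 1L) {
  # proportions of non-mixed cells; mixed cluster (~10% of all cells) is
  # generated via mixed_fraction. T: 0/1/3/4, myeloid: 5/6/7/12/13,
  # SMC: 8, EC: 9/10, B: 11.
  props <- c(T0 = 0.200, T1 = 0.140, T3 = 0.110, T4 = 0.074,
             My5 = 0.060, My6 = 0.050, My7 = 0.040, My12 = 0.020, My13 = 0.015,
             SMC8 = 0.050, EC9 = 0.045, EC10 = 0.035, B11 = 0.061)
  props <- props / sum(props)
  mixed_fraction <- 0.10
  n_real <- round(n_cells * (1 - mixed_fraction))
  sizes <- pmax(2L, round(props * n_real))
  pops <- make_populations(names(props), sizes, n_markers, marker_fold, n_genes)
  simulation_design(n_genes, pops, mixed_fraction = mixed_fraction,
                    seed = seed)
}

#' Simulate counts, cluster truth and a marker truth table
#'
#' For gene g in cell c of population p,
#' `count ~ NB(mean = s_c * mu_g * f_gp, dispersion = phi)` with per-cell
#' size factor `s_c` log-normal, per-gene baseline `mu_g` log-normal, and
#' `f_gp = marker_fold` iff g is a marker of p (else 1). Mixed cells average
#' the mean vectors of two distinct random populations.
#'
#' @param design A [simulation_design()].
#' @return List with `counts` (validated count matrix), `clusters` (named
#'   factor), and `truth` (`data.frame` gene/population/fold recording every
#'   planted marker).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    genes <- design$genes
    G <- design$n_genes
    mu <- stats::rlnorm(G, design$baseline_mean_logmu, design$baseline_mean_logsigma)
    names(mu) <- genes
    pops <- design$populations
    P <- length(pops)
    # per-population mean vectors
    pop_means <- vapply(pops, function(p) {
      f <- rep(1, G)
      f[match(p$markers, genes)] <- p$marker_fold
      mu * f
    }, numeric(G))
    n_real <- sum(vapply(pops, function(p) as.numeric(p$n_cells), numeric(1)))
    n_mixed <- round(design$mixed_fraction / (1 - design$mixed_fraction) * n_real)
    N <- n_real + n_mixed
    s <- stats::rlnorm(N, 0, design$libsize_logsigma)
    labels <- character(N)
    mean_mat <- matrix(0, G, N)
    idx <- 1L
    for (j in seq_len(P)) {
      n <- pops[[j]]$n_cells
      cols <- idx:(idx + n - 1L)
      mean_mat[, cols] <- pop_means[, j]
      labels[cols] <- pops[[j]]$label
      idx <- idx + n
    }
    if (n_mixed > 0) {
      for (c in idx:N) {
        pick <- sample.int(P, 2)
        mean_mat[, c] <- (pop_means[, pick[1]] + pop_means[, pick[2]]) / 2
        labels[c] <- if (design$mixed_assign == "mixed") "Mixed" else pops[[pick[1]]]$label
      }
    }
    mean_mat <- sweep(mean_mat, 2, s, `*`)
    counts <- matrix(stats::rnbinom(G * N, mu = mean_mat,
                                    size = 1 / design$dispersion),
                     nrow = G)
    barcodes <- sprintf("cell%05d", seq_len(N))
    cm <- count_matrix(counts, genes = genes, barcodes = barcodes)
    truth <- do.call(rbind, lapply(pops, function(p) {
      if (length(p$markers) == 0) return(NULL)
      data.frame(gene = p$markers, population = p$label,
                 fold = p$marker_fold, stringsAsFactors = FALSE)
    }))
    list(counts = cm,
         clusters = cluster_assignment(barcodes, labels),
         truth = truth)
  })
}

#' Specify a GWAS summary-statistics fixture
#'
#' Genes are tiled along chromosomes at a fixed spacing; each planted gene
#' receives at least one genome-wide-significant variant inside its body,
#' while decoy variants with null p-values are scattered at a given density.
#'
#' @param genes Character vector of gene symbols to tile (typically the
#'   simulated expression genes, so candidate genes overlap the atlas).
#' @param planted_genes Genes to receive significant variants (subset of
#'   `genes`).
#' @param n_loci How many planted genes receive a locus; default all.
#' @param gene_spacing Distance between consecutive gene starts, bp. The
#'   default (600 kb) exceeds the default clumping merge distance, so a
#'   locus never straddles a neighbouring gene.
#' @param gene_length Gene body length, bp.
#' @param n_chrom Number of chromosomes the genes are tiled over.
#' @param decoy_density Decoy variants per megabase (null p-values).
#' @param sig_pval_range Range the planted (significant) p-values are drawn
#'   from; must sit entirely below genome-wide significance.
#' @param null_pval_range Range for decoy p-values; entirely above threshold.
#' @param maf_range Uniform range for minor allele frequencies.
#' @param noncoding_every Every k-th non-planted gene is annotated `lncRNA`
#'   instead of `protein_coding`, to exercise biotype filtering.
#' @param seed Integer seed.
#' @return A `gwas_fixture_design` list.
#' @export
gwas_fixture_design <- function(genes, planted_genes, n_loci = length(planted_genes),
                                gene_spacing = 600000, gene_length = 20000,
                                n_chrom = 4, decoy_density = 2,
                                sig_pval_range = c(1e-12, 1e-9),
                                null_pval_range = c(1e-4, 1),
                                maf_range = c(0.05, 0.5),
                                noncoding_every = 5,
                                seed = 1L) {
  stopifnot(all(planted_genes %in% genes), gene_length < gene_spacing,
            max(sig_pval_range) < 5e-8, min(null_pval_range) > 5e-8)
  if (n_loci > length(planted_genes)) {
    pm_stop("n_loci (", n_loci, ") exceeds the number of planted genes (",
            length(planted_genes), ")")
  }
  structure(list(genes = genes, planted_genes = planted_genes, n_loci = n_loci,
                 gene_spacing = gene_spacing, gene_length = gene_length,
                 n_chrom = n_chrom, decoy_density = decoy_density,
                 sig_pval_range = sig_pval_range,
                 null_pval_range = null_pval_range,
                 maf_range = maf_range, noncoding_every = noncoding_every,
                 seed = as.integer(seed)),
            class = "gwas_fixture_design")
}

#' Simulate a GWAS table plus matching gene annotation
#'
#' @param fix A [gwas_fixture_design()].
#' @return List with `gwas` (summary-statistics `data.frame` in
#'   [read_gwas()] layout), `annot` (BED-convention gene annotation) and
#'   `planted` (the genes that received significant variants).
#' @export
simulate_gwas <- function(fix) {
  stopifnot(inherits(fix, "gwas_fixture_design"))
  with_seed(fix$seed, {
    genes <- fix$genes
    G <- length(genes)
    per_chrom <- ceiling(G / fix$n_chrom)
    chrom <- paste0("chr", ((seq_len(G) - 1) %/% per_chrom) + 1)
    slot <- (seq_len(G) - 1) %% per_chrom
    start <- slot * fix$gene_spacing + 10000L      # 0-based
    end <- start + fix$gene_length                  # exclusive
    biotype <- rep("protein_coding", G)
    nonplanted <- which(!(genes %in% fix$planted_genes))
    if (fix$noncoding_every > 0 && length(nonplanted) > 0) {
      biotype[nonplanted[seq_along(nonplanted) %% fix$noncoding_every == 0]] <- "lncRNA"
    }
    annot <- gene_annotation(data.frame(
      gene = genes, chrom = chrom, start = start, end = end,
      strand = ".", biotype = biotype, stringsAsFactors = FALSE))
    planted <- fix$planted_genes[seq_len(fix$n_loci)]
    rows <- list()
    for (g in planted) {
      i <- match(g, genes)
      pos1 <- start[i] + sample.int(fix$gene_length, 1)  # 1-based, inside body
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom[i], pos = pos1,
        variant_id = paste0("rs_sig_", g),
        pval = exp(stats::runif(1, log(fix$sig_pval_range[1]),
                                log(fix$sig_pval_range[2]))),
        maf = stats::runif(1, fix$maf_range[1], fix$maf_range[2]),
        stringsAsFactors = FALSE)
    }
    chrom_len <- per_chrom * fix$gene_spacing + 20000
    n_decoys <- round(fix$decoy_density * fix$n_chrom * chrom_len / 1e6)
    if (n_decoys > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = paste0("chr", sample.int(fix$n_chrom, n_decoys, replace = TRUE)),
        pos = sample.int(chrom_len, n_decoys, replace = TRUE),
        variant_id = paste0("rs_null_", seq_len(n_decoys)),
        pval = exp(stats::runif(n_decoys, log(fix$null_pval_range[1]),
                                log(fix$null_pval_range[2]))),
        maf = stats::runif(n_decoys, fix$maf_range[1], fix$maf_range[2]),
        stringsAsFactors = FALSE)
    }
    gwas <- do.call(rbind, rows)
    gwas <- gwas[order(gwas$chrom, gwas$pos), , drop = FALSE]
    rownames(gwas) <- NULL
    list(gwas = gwas, annot = annot, planted = planted)
  })
}

#' Plant a candidate gene set enriched for a target population's markers
#'
#' Draws `ceiling(enrich_frac * n_candidates)` genes from the markers of the
#' target population(s) and the remainder uniformly from all other genes
#' (genes that are not markers of the target; markers of other populations
#' remain eligible).
#'
#' @param truth Marker truth table from [simulate_counts()].
#' @param genes All gene symbols of the dataset (the sampling frame).
#' @param pattern_target Population label(s) whose markers are enriched.
#' @param n_candidates Total candidate genes to draw.
#' @param enrich_frac Fraction of candidates drawn from target markers.
#' @param seed Integer seed.
#' @return Character vector of candidate genes.
#' @export
plant_candidate_set <- function(truth, genes, pattern_target, n_candidates,
                                enrich_frac, seed = 1L) {
  stopifnot(enrich_frac >= 0, enrich_frac <= 1, n_candidates >= 1)
  target_markers <- truth$gene[truth$population %in% pattern_target]
  n_target <- ceiling(enrich_frac * n_candidates)
  if (n_target > length(target_markers)) {
    pm_stop("insufficient target markers: need ", n_target, ", have ",
            length(target_markers))
  }
  other <- setdiff(genes, target_markers)
  if (n_candidates - n_target > length(other)) pm_stop("not enough non-target genes")
  with_seed(seed, {
    c(if (n_target > 0) sample(target_markers, n_target) else character(0),
      sample(other, n_candidates - n_target))
  })
}
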