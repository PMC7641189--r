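## Pipeline orchestration: one declarative config drives
## simulate -> degs -> patterns -> map-loci -> enrich (-> crossmap), with
## per-stage seeds derived from a master seed and a consolidated report.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' documented default; the demo runs the bundled 14-population plaque
#' preset with a planted candidate set targeting the endothelial
#' populations.
#'
#' @param master_seed Master seed; per-stage seeds are derived from it by
#'   hashing the stage name, so adding a stage never perturbs the others.
#' @return Nested configuration list.
#' @export
default_config <- function(master_seed = 42L) {
  list(
    master_seed = as.integer(master_seed),
    outdir = "plaqmap_out",
    simulate = list(enabled = TRUE, preset = "plaque", n_cells = 3282,
                    n_genes = 2000, n_markers = 15, marker_fold = 4),
    inputs = list(counts_dir = NULL, dense_tsv = NULL, clusters_tsv = NULL,
                  gwas_tsv = NULL, annotation_bed = NULL, gene_list = NULL),
    candidates = list(target = c("EC9", "EC10"), n_candidates = 30,
                      enrich_frac = 0.4),
    gwas_fixture = list(gene_spacing = 600000, gene_length = 20000,
                        n_chrom = 4, decoy_density = 2),
    degs = list(alpha = 0.05, lfc_min = 0.25, min_cells = 3),
    patterns = list(k = 15, restarts = 50, z_annot = 1.0),
    map_loci = list(p_thresh = 5e-8, maf_min = 0.01, merge_dist = 500000,
                    window = 100000, biotype = "protein_coding"),
    enrich = list(n_perm = 10000),
    crossmap = list(enabled = FALSE, ref_deg_tsv = NULL, top_n = 100,
                    mode = "casefold")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its documented default.
#'
#' @param path Path to a YAML configuration file.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) pm_stop("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) pm_stop("unparseable config: ",
                                               conditionMessage(e)))
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_cfg(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' Checks every stage parameter against its module's preconditions before
#' any stage runs. Each violation names the field, the constraint and the
#' offending value.
#'
#' @param config Configuration list (or a YAML path).
#' @return `TRUE` when valid, otherwise a character vector of violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  v <- character(0)
  chk <- function(ok, field, constraint, value) {
    if (!isTRUE(ok)) v <<- c(v, paste0(field, " must ", constraint,
                                       " (got ", value, ")"))
  }
  chk(is.numeric(config$master_seed), "master_seed", "be numeric",
      config$master_seed)
  chk(config$patterns$k >= 2, "patterns.k", "be >= 2", config$patterns$k)
  chk(config$patterns$restarts >= 1, "patterns.restarts", "be >= 1",
      config$patterns$restarts)
  chk(config$degs$alpha > 0 && config$degs$alpha < 1, "degs.alpha",
      "lie in (0, 1)", config$degs$alpha)
  chk(config$degs$lfc_min >= 0, "degs.lfc_min", "be >= 0", config$degs$lfc_min)
  chk(config$degs$min_cells >= 1, "degs.min_cells", "be >= 1",
      config$degs$min_cells)
  chk(config$map_loci$p_thresh > 0 && config$map_loci$p_thresh < 1,
      "map_loci.p_thresh", "lie in (0, 1)", config$map_loci$p_thresh)
  chk(config$map_loci$maf_min >= 0 && config$map_loci$maf_min <= 0.5,
      "map_loci.maf_min", "lie in [0, 0.5]", config$map_loci$maf_min)
  chk(config$map_loci$merge_dist > 0, "map_loci.merge_dist", "be > 0",
      config$map_loci$merge_dist)
  chk(config$map_loci$window >= 0, "map_loci.window", "be >= 0",
      config$map_loci$window)
  chk(config$enrich$n_perm >= 100, "enrich.n_perm", "be >= 100",
      config$enrich$n_perm)
  chk(config$candidates$enrich_frac >= 0 && config$candidates$enrich_frac <= 1,
      "candidates.enrich_frac", "lie in [0, 1]", config$candidates$enrich_frac)
  chk(config$candidates$n_candidates >= 1, "candidates.n_candidates",
      "be >= 1", config$candidates$n_candidates)
  if (isTRUE(config$simulate$enabled)) {
    chk(config$simulate$n_genes >= config$patterns$k, "simulate.n_genes",
        "be >= patterns.k", config$simulate$n_genes)
    chk(config$simulate$marker_fold > 1, "simulate.marker_fold", "be > 1",
        config$simulate$marker_fold)
  }
  if (length(v) == 0) TRUE else v
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (simulate or load inputs, then
#' differential expression, pattern building, locus mapping, enrichment and
#' optionally cross-dataset mapping), writing each stage's TSV outputs
#' before the next stage starts, and returns a consolidated report. The run
#' is fully deterministic under a fixed `master_seed`.
#'
#' @param config Configuration list ([default_config()] /
#'   [load_config()]) or a YAML path.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return A `run_report` list: per-stage record counts, enrichment tables,
#'   package version and the configuration echo. Per-stage wall-clock times
#'   are reported on the console log only, so that the written outputs are
#'   byte-reproducible.
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  if (is.character(config)) config <- load_config(config)
  ok <- validate_config(config)
  if (!isTRUE(ok)) pm_stop("invalid config:\n  ", paste(ok, collapse = "\n  "))
  if (is.null(outdir)) outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ms <- config$master_seed
  counts_rec <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e) {
      pm_stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }

  ## -- simulate / load ------------------------------------------------
  sim <- stage("simulate", {
    if (isTRUE(config$simulate$enabled)) {
      sc <- config$simulate
      des <- plaque_preset(n_cells = sc$n_cells, n_genes = sc$n_genes,
                           n_markers = sc$n_markers,
                           marker_fold = sc$marker_fold,
                           seed = stage_seed(ms, "simulate"))
      s <- simulate_counts(des)
      write_counts(s$counts, file.path(outdir, "counts"))
      write_clusters(s$clusters, file.path(outdir, "clusters.tsv"))
      write_tsv(s$truth, file.path(outdir, "truth_markers.tsv"))
      s
    } else {
      inp <- config$inputs
      cm <- if (!is.null(inp$dense_tsv)) read_counts(path_dense_tsv = inp$dense_tsv)
      else read_counts(file.path(inp$counts_dir, "matrix.mtx"),
                       file.path(inp$counts_dir, "genes.tsv"),
                       file.path(inp$counts_dir, "barcodes.tsv"))
      list(counts = cm,
           clusters = read_clusters(inp$clusters_tsv, cm),
           truth = NULL)
    }
  })
  counts_rec$n_cells <- ncol(sim$counts)
  counts_rec$n_genes <- nrow(sim$counts)
  counts_rec$n_clusters <- nlevels(sim$clusters)

  ## -- differential expression ----------------------------------------
  deg <- stage("degs", {
    norm <- normalize_counts(sim$counts)
    d <- find_degs(norm, sim$clusters, alpha = config$degs$alpha,
                   lfc_min = config$degs$lfc_min,
                   min_cells_expressing = config$degs$min_cells)
    write_deg_table(d, file.path(outdir, "degs.tsv"))
    write_run_metadata(file.path(outdir, "degs.tsv"),
                       params = config$degs,
                       counts = list(universe = length(attr(d, "universe")),
                                     degs = length(deg_genes(d))))
    attr(d, "norm") <- norm
    d
  })
  universe <- attr(deg, "universe")
  deg_set <- deg_genes(deg)
  counts_rec$n_universe <- length(universe)
  counts_rec$n_degs <- length(deg_set)

  ## -- patterns --------------------------------------------------------
  patterns <- stage("patterns", {
    prof <- mean_profiles(attr(deg, "norm"), sim$clusters)
    z <- zscore_profiles(prof, deg_set)
    ps <- build_patterns(z, K = config$patterns$k,
                         n_restarts = config$patterns$restarts,
                         seed = stage_seed(ms, "patterns"))
    ps <- annotate_patterns(ps, z_annot = config$patterns$z_annot)
    write_patterns(ps, file.path(outdir, "pattern_members.tsv"),
                   file.path(outdir, "pattern_centroids.tsv"))
    ps
  })
  counts_rec$n_patterns <- patterns$K

  ## -- locus mapping ----------------------------------------------------
  cand <- stage("map-loci", {
    ml <- config$map_loci
    if (!is.null(config$inputs$gene_list)) {
      genes <- readLines(config$inputs$gene_list)
      writeLines(genes, file.path(outdir, "candidate_genes.txt"))
      list(genes = genes, loci = NULL)
    } else {
      if (isTRUE(config$simulate$enabled)) {
        cc <- config$candidates
        planted <- plant_candidate_set(sim$truth, rownames(sim$counts),
                                       cc$target, cc$n_candidates,
                                       cc$enrich_frac,
                                       seed = stage_seed(ms, "candidates"))
        gf <- config$gwas_fixture
        fix <- gwas_fixture_design(rownames(sim$counts), planted,
                                   gene_spacing = gf$gene_spacing,
                                   gene_length = gf$gene_length,
                                   n_chrom = gf$n_chrom,
                                   decoy_density = gf$decoy_density,
                                   seed = stage_seed(ms, "gwas"))
        g <- simulate_gwas(fix)
        write_gwas(g$gwas, file.path(outdir, "gwas.tsv"))
        write_gene_annotation(g$annot, file.path(outdir, "annotation.bed"))
        gwas <- g$gwas; annot <- g$annot
      } else {
        gwas <- read_gwas(config$inputs$gwas_tsv)
        annot <- read_gene_annotation(config$inputs$annotation_bed)
      }
      loci <- clump_loci(gwas, p_thresh = ml$p_thresh, maf_min = ml$maf_min,
                         merge_dist = ml$merge_dist)
      write_tsv(loci, file.path(outdir, "loci.tsv"))
      mapped <- map_genes(loci, annot, window = ml$window,
                          biotype = ml$biotype)
      write_tsv(mapped, file.path(outdir, "candidate_genes.tsv"))
      list(genes = mapped$gene, loci = loci)
    }
  })
  counts_rec$n_loci <- if (is.null(cand$loci)) NA_integer_ else nrow(cand$loci)
  counts_rec$n_candidate_genes <- length(cand$genes)

  ## -- enrichment -------------------------------------------------------
  enr <- stage("enrich", {
    np <- config$enrich$n_perm
    glob <- global_overlap_test(cand$genes, deg_set, universe,
                                n_perm = np, seed = stage_seed(ms, "enrich"))
    per_pat <- pattern_accumulation_test(cand$genes, patterns, deg_set,
                                         n_perm = np,
                                         seed = stage_seed(ms, "enrich_pattern"))
    summ <- summarize_enrichment(list(glob, per_pat))
    write_tsv(summ, file.path(outdir, "enrichment.tsv"))
    list(global = glob, per_pattern = per_pat, summary = summ)
  })
  counts_rec$n_overlap_genes <- enr$global$n_observed_overlap

  ## -- crossmap (optional) ----------------------------------------------
  cross <- NULL
  if (isTRUE(config$crossmap$enabled)) {
    cross <- stage("crossmap", {
      ref_deg <- read_deg_table(config$crossmap$ref_deg_tsv)
      q_mark <- marker_table(deg, top_n = config$crossmap$top_n)
      r_mark <- marker_table(ref_deg, top_n = config$crossmap$top_n)
      h <- harmonize_genes(universe, unique(ref_deg$gene),
                           mode = config$crossmap$mode)
      cm <- crossmap_clusters(q_mark, r_mark, h,
                              top_n = config$crossmap$top_n)
      write_tsv(cm$calls, file.path(outdir, "crossmap_calls.tsv"))
      write_tsv(cm$top5, file.path(outdir, "crossmap_top5.tsv"))
      cm
    })
  }

  cfg_echo <- config
  cfg_echo$outdir <- NULL # not part of the results; keeps reruns byte-stable
  report <- structure(list(
    counts = counts_rec,
    pattern_sizes = patterns$sizes,
    pattern_annotations = lapply(patterns$annotations, identity),
    enrichment = list(global = as.data.frame(enr$global),
                      per_pattern = as.data.frame(enr$per_pattern)),
    crossmap = if (is.null(cross)) NULL else cross$calls,
    version = as.character(utils::packageVersion("plaqmap")),
    config = cfg_echo
  ), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  report
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("plaqmap run report (v", x$version, ")\n", sep = "")
  cc <- x$counts
  cat("  cells:", cc$n_cells, " genes:", cc$n_genes,
      " clusters:", cc$n_clusters, "\n")
  cat("  gene universe:", cc$n_universe, " DEG set:", cc$n_degs,
      " patterns:", cc$n_patterns, "\n")
  cat("  loci:", cc$n_loci, " candidate genes:", cc$n_candidate_genes,
      " overlap with DEGs:", cc$n_overlap_genes, "\n")
  g <- x$enrichment$global
  cat(sprintf("  global enrichment: fold %.2f, p_perm = %.3g, p_hyper = %.3g\n",
              g$fold_enrichment, g$p_perm, g$p_hyper))
  pp <- x$enrichment$per_pattern
  best <- which.min(pp$p_perm)
  ann <- paste(x$pattern_annotations[[best]], collapse = ", ")
  cat(sprintf("  top pattern: %s [%s], p_perm = %.3g\n",
              pp$scope[best], ann, pp$p_perm[best]))
  invisible(x)
}
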