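## GWAS locus definition and positional candidate-gene mapping:
## distance-based clumping of genome-wide-significant variants into loci,
## then protein-coding genes within a window of each locus.

#' Clump significant GWAS variants into loci
#'
#' Variants are filtered to `pval <= p_thresh` and `maf >= maf_min` (missing
#' MAF passes). Per chromosome, greedy clumping: the most significant
#' unassigned variant becomes a lead, absorbing every remaining significant
#' variant within `merge_dist` of it; repeat until none remain. The locus
#' span is the min/max position of its member variants (1-based inclusive).
#'
#' @param gwas GWAS table from [read_gwas()] (sorted by chrom, pos).
#' @param p_thresh Genome-wide significance threshold (default 5e-8).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param merge_dist Absorption distance around the lead, bp (default 5e5).
#' @return `data.frame` of loci: locus_id, chrom, start, end,
#'   lead_variant_id, lead_pval, n_variants; ordered by (chrom, start).
#'   Empty (with a warning) when no variant is significant.
#' @export
clump_loci <- function(gwas, p_thresh = 5e-8, maf_min = 0.01,
                       merge_dist = 500000) {
  maf_ok <- is.na(gwas$maf) | gwas$maf >= maf_min
  sig <- gwas[gwas$pval <= p_thresh & maf_ok, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant variants at p <= ", p_thresh)
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_variant_id = character(0), lead_pval = numeric(0),
                      n_variants = integer(0), stringsAsFactors = FALSE))
  }
  loci <- list()
  for (ch in unique(sig$chrom)) {
    v <- sig[sig$chrom == ch, , drop = FALSE]
    # deterministic lead choice: smallest p, ties by position
    v <- v[order(v$pval, v$pos), , drop = FALSE]
    while (nrow(v) > 0) {
      lead <- v[1, ]
      member <- abs(v$pos - lead$pos) <= merge_dist
      grp <- v[member, , drop = FALSE]
      loci[[length(loci) + 1]] <- data.frame(
        chrom = ch, start = min(grp$pos), end = max(grp$pos),
        lead_variant_id = lead$variant_id, lead_pval = lead$pval,
        n_variants = nrow(grp), stringsAsFactors = FALSE)
      v <- v[!member, , drop = FALSE]
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_id = sprintf("locus%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map candidate genes to loci by position
#'
#' A gene is a candidate for a locus when its biotype matches and its body,
#' extended by `window` on both sides, intersects the locus interval
#' (interval math in 0-based half-open coordinates; loci are converted from
#' their 1-based inclusive spans). `distance_bp` is 0 when the gene body
#' overlaps the locus, otherwise the bp gap. A gene mapping to several loci
#' is reported once, keeping the row with minimal distance.
#'
#' @param loci Locus table from [clump_loci()].
#' @param annot Gene annotation ([gene_annotation()] / BED convention).
#' @param window Flanking window around the gene body, bp (default 1e5).
#' @param biotype Biotype to keep (default `"protein_coding"`).
#' @return `data.frame` with columns gene, locus_id, distance_bp, one row
#'   per candidate gene.
#' @export
map_genes <- function(loci, annot, window = 100000, biotype = "protein_coding") {
  if (nrow(loci) == 0) {
    return(data.frame(gene = character(0), locus_id = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  }
  unknown <- !(loci$chrom %in% annot$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " locus/loci on chromosome(s) absent ",
            "from the annotation: ",
            paste(unique(loci$chrom[unknown]), collapse = ", "))
    loci <- loci[!unknown, , drop = FALSE]
  }
  ann <- annot[annot$biotype == biotype, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l0 <- loci$start[i] - 1L  # 0-based half-open locus interval
    l1 <- loci$end[i]
    a <- ann[ann$chrom == loci$chrom[i], , drop = FALSE]
    hit <- (a$start - window) < l1 & (a$end + window) > l0
    a <- a[hit, , drop = FALSE]
    if (nrow(a) == 0) next
    gap <- pmax(0L, pmax(a$start - l1, l0 - a$end))
    rows[[length(rows) + 1]] <- data.frame(
      gene = a$gene, locus_id = loci$locus_id[i], distance_bp = as.integer(gap),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), locus_id = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # deduplicate across loci, keeping minimal distance (ties: first locus)
  out <- out[order(out$gene, out$distance_bp, out$locus_id), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  out <- out[order(out$locus_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
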