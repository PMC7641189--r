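## On-disk formats: sparse/dense counts, cluster labels, GWAS summary
## statistics, BED-style gene annotation. All readers validate strictly and
## report every dropped record; all writer/reader pairs round-trip losslessly.

#' Construct and validate a gene-by-cell count matrix
#'
#' The package's working container for single-cell counts is a sparse
#' [Matrix::dgCMatrix] with gene symbols as row names and cell barcodes as
#' column names. This constructor enforces the container's invariants:
#' unique non-empty gene symbols, unique barcodes, and non-negative integral
#' entries.
#'
#' @param counts A matrix or sparse Matrix of counts (genes x cells).
#' @param genes Character vector of gene symbols (row identities). Defaults
#'   to `rownames(counts)`.
#' @param barcodes Character vector of cell barcodes (column identities).
#'   Defaults to `colnames(counts)`.
#' @return A validated `dgCMatrix` with `genes` as rownames and `barcodes`
#'   as colnames.
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3,
#'                          dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
#' sum(m)
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         barcodes = colnames(counts)) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(barcodes)) {
    pm_validation_error("count matrix requires gene and barcode identifiers")
  }
  genes <- as.character(genes)
  barcodes <- as.character(barcodes)
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    pm_format_error("dimension mismatch: matrix is ", nrow(m), "x", ncol(m),
                    " but ", length(genes), " genes / ", length(barcodes),
                    " barcodes were supplied")
  }
  if (anyDuplicated(genes)) {
    pm_validation_error("duplicate gene symbols: ",
                        paste(utils::head(unique(genes[duplicated(genes)]), 5),
                              collapse = ", "))
  }
  if (any(!nzchar(genes))) pm_validation_error("empty gene symbol")
  if (anyDuplicated(barcodes)) {
    pm_validation_error("duplicate barcodes: ",
                        paste(utils::head(unique(barcodes[duplicated(barcodes)]), 5),
                              collapse = ", "))
  }
  v <- m@x
  if (any(v < 0)) pm_validation_error("negative count entries")
  if (any(v != round(v))) pm_validation_error("non-integer count entries")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Read a count matrix from Matrix Market or dense TSV files
#'
#' Either supply `path_matrix`, `path_genes` and `path_barcodes` (Matrix
#' Market `.mtx` with one-column gene and barcode TSVs, the conventional
#' CellRanger-style triplet), or `path_dense_tsv` alone (genes in rows,
#' cells in columns, first column = gene symbol, header row = barcodes).
#'
#' @param path_matrix Path to an `.mtx` Matrix Market file (genes x cells).
#' @param path_genes Path to a TSV whose first column holds gene symbols.
#' @param path_barcodes Path to a TSV whose first column holds barcodes.
#' @param path_dense_tsv Path to a dense TSV alternative to the MTX triplet.
#' @return A validated count matrix (see [count_matrix()]); gene and barcode
#'   order is preserved from the files.
#' @export
read_counts <- function(path_matrix = NULL, path_genes = NULL,
                        path_barcodes = NULL, path_dense_tsv = NULL) {
  if (!is.null(path_dense_tsv)) {
    df <- utils::read.delim(path_dense_tsv, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) pm_format_error("dense counts TSV needs a gene column plus >=1 cell column")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    return(count_matrix(m, genes = genes, barcodes = colnames(df)[-1]))
  }
  for (p in c(path_matrix, path_genes, path_barcodes)) {
    if (!file.exists(p)) pm_format_error("file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(path_matrix),
                error = function(e) pm_format_error("invalid MTX file: ", conditionMessage(e)))
  genes <- utils::read.delim(path_genes, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(path_barcodes, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    pm_format_error("dimension mismatch: MTX declares ", nrow(m), "x", ncol(m),
                    " but id files have ", length(genes), " genes / ",
                    length(barcodes), " barcodes")
  }
  count_matrix(m, genes = genes, barcodes = barcodes)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` under `dir`.
#'
#' @param counts A validated count matrix.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, "matrix.mtx")
  pg <- file.path(dir, "genes.tsv")
  pb <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(counts, pm)
  writeLines(rownames(counts), pg)
  writeLines(colnames(counts), pb)
  invisible(c(matrix = pm, genes = pg, barcodes = pb))
}

#' Read cell-to-cluster assignments
#'
#' Reads a two-column TSV (barcode, cluster label), intersects it with the
#' barcodes of `counts`, and returns a named factor mapping barcode to
#' cluster. Barcodes absent from `counts` are dropped with a message; the
#' dropped count is attached as attribute `n_dropped`.
#'
#' @param path_tsv Path to the two-column TSV.
#' @param counts Companion count matrix whose barcodes define the valid set.
#' @param header Does the file carry a header row?
#' @return Named factor of cluster labels, names = barcodes, ordered as in
#'   `counts`; attribute `n_dropped` reports discarded rows.
#' @export
read_clusters <- function(path_tsv, counts, header = FALSE) {
  df <- utils::read.delim(path_tsv, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) pm_format_error("cluster TSV needs two columns (barcode, label)")
  bc <- as.character(df[[1]])
  lab <- as.character(df[[2]])
  if (anyDuplicated(bc)) {
    pm_validation_error("duplicate barcode rows in cluster file: ",
                        paste(utils::head(unique(bc[duplicated(bc)]), 5), collapse = ", "))
  }
  keep <- bc %in% colnames(counts)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("read_clusters: dropped ", n_dropped,
            " barcode(s) absent from the count matrix")
  }
  bc <- bc[keep]
  lab <- lab[keep]
  if (length(bc) == 0) pm_validation_error("no cluster barcodes overlap the count matrix")
  cl <- cluster_assignment(bc, lab)
  # order as in counts, restricted to labelled cells
  cl <- cl[colnames(counts)[colnames(counts) %in% names(cl)]]
  cl <- droplevels(cl)
  if (nlevels(cl) < 2) pm_validation_error("need >=2 clusters, got ", nlevels(cl))
  attr(cl, "n_dropped") <- n_dropped
  cl
}

#' Construct a cluster assignment
#'
#' @param barcodes Character vector of cell barcodes.
#' @param labels Character vector of cluster labels, parallel to `barcodes`.
#' @return Named factor (names = barcodes).
#' @export
cluster_assignment <- function(barcodes, labels) {
  stopifnot(length(barcodes) == length(labels))
  if (anyDuplicated(barcodes)) pm_validation_error("duplicate barcodes in cluster assignment")
  f <- factor(as.character(labels))
  names(f) <- as.character(barcodes)
  f
}

#' Write a cluster assignment as a two-column TSV
#' @param clusters Named factor as returned by [read_clusters()].
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  write_tsv(data.frame(barcode = names(clusters),
                       cluster = as.character(clusters),
                       stringsAsFactors = FALSE), path)
}

#' Read GWAS summary statistics
#'
#' Parses a tab-delimited summary-statistics table into the standard
#' five-column layout (`chrom`, `pos`, `variant_id`, `pval`, `maf`), using
#' `column_map` to bind those roles to the file's own header names. Rows with
#' a p-value outside (0, 1] or a MAF outside \[0, 0.5\] are rejected with a
#' message; missing MAF is allowed (recorded as `NA`) since many public
#' tables omit it. Output is sorted by (chrom, pos); positions are 1-based.
#'
#' @param path_tsv Path to the summary-statistics TSV.
#' @param column_map Named character vector or list binding
#'   `c(chrom=, pos=, id=, pval=, maf=)` to header names; `maf` may be
#'   omitted.
#' @return `data.frame` with columns chrom, pos, variant_id, pval, maf;
#'   attribute `n_rejected` counts discarded rows.
#' @export
read_gwas <- function(path_tsv,
                      column_map = c(chrom = "chrom", pos = "pos", id = "id",
                                     pval = "pval", maf = "maf")) {
  df <- read_tsv(path_tsv)
  column_map <- as.list(column_map)
  for (role in c("chrom", "pos", "id", "pval")) {
    if (is.null(column_map[[role]]) || !(column_map[[role]] %in% names(df))) {
      pm_format_error("GWAS table is missing mandatory column for '", role, "'")
    }
  }
  out <- data.frame(
    chrom = as.character(df[[column_map$chrom]]),
    pos = as.integer(df[[column_map$pos]]),
    variant_id = as.character(df[[column_map$id]]),
    pval = as.numeric(df[[column_map$pval]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(column_map$maf) && column_map$maf %in% names(df)) {
    out$maf <- as.numeric(df[[column_map$maf]])
  } else {
    out$maf <- NA_real_
    message("read_gwas: no MAF column; all variants treated as passing MAF filters")
  }
  bad <- is.na(out$pval) | out$pval <= 0 | out$pval > 1 |
    is.na(out$pos) | out$pos < 1 |
    (!is.na(out$maf) & (out$maf < 0 | out$maf > 0.5))
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    message("read_gwas: rejected ", n_rejected, " invalid row(s)")
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a GWAS table
#' @param gwas GWAS table as returned by [read_gwas()].
#' @param path Output path.
#' @export
write_gwas <- function(gwas, path) {
  out <- gwas[, c("chrom", "pos", "variant_id", "pval", "maf")]
  names(out)[3] <- "id" # default read_gwas column map: lossless round trip
  write_tsv(out, path)
}

#' Read gene annotation from a BED6+1 file
#'
#' Standard BED conventions: 0-based, half-open intervals; columns chrom,
#' start, end, gene (name), score (ignored), strand, biotype.
#'
#' @param path Path to the BED6+1 file (no header).
#' @return `data.frame` with columns gene, chrom, start, end, strand,
#'   biotype.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7) pm_format_error("gene annotation must be BED6+1 (7 columns)")
  out <- data.frame(
    gene = as.character(df[[4]]),
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    strand = as.character(df[[6]]),
    biotype = as.character(df[[7]]),
    stringsAsFactors = FALSE
  )
  gene_annotation(out)
}

#' Validate a gene-annotation table
#'
#' @param annot `data.frame` with columns gene, chrom, start (0-based),
#'   end (exclusive), strand, biotype.
#' @return The validated table.
#' @export
gene_annotation <- function(annot) {
  need <- c("gene", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(annot))) {
    pm_format_error("gene annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(annot$gene)) pm_validation_error("duplicate gene symbols in annotation")
  if (any(annot$start >= annot$end)) pm_validation_error("annotation has start >= end")
  if (!all(annot$strand %in% c("+", "-", "."))) {
    pm_validation_error("strand must be one of +, -, .")
  }
  rownames(annot) <- NULL
  annot
}

#' Write gene annotation as BED6+1
#' @param annot Validated annotation table.
#' @param path Output path.
#' @export
write_gene_annotation <- function(annot, path) {
  bed <- data.frame(annot$chrom, annot$start, annot$end, annot$gene,
                    0L, annot$strand, annot$biotype)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON run-metadata sidecar
#'
#' Records the package version, timestamp-free parameter echo and record
#' counts next to a result table so runs are auditable.
#'
#' @param path Path of the artifact the sidecar describes; the sidecar is
#'   written to `paste0(path, ".meta.json")`.
#' @param params Named list of parameters to echo.
#' @param counts Named list of record counts.
#' @return Invisibly, the sidecar path.
#' @export
write_run_metadata <- function(path, params = list(), counts = list()) {
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(
    list(artifact = basename(path),
         package = "plaqmap",
         version = as.character(utils::packageVersion("plaqmap")),
         params = params, counts = counts),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
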