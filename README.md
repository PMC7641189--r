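# plaqmap

Mapping GWAS risk loci to the cell populations of a single-cell RNA-seq
atlas.

Genome-wide association studies deliver risk loci, not mechanisms: a locus
names a stretch of genome, and the genes and cell types through which it
acts remain to be established. `plaqmap` implements the workflow used to
connect coronary-artery-disease loci to the cell populations of the
atherosclerotic plaque: positional candidate genes are read off the GWAS
summary statistics, the single-cell atlas is summarized into per-cluster
differential expression and population-matched expression patterns, and the
candidate set is tested for accumulation in specific patterns — pointing at
the cell types (macrophages, endothelium, smooth muscle) where the risk
genes are actually expressed. The package is aimed at analysts who have a
clustered single-cell dataset and a GWAS summary-statistics table and want
a transparent, fully reproducible locus-to-cell-type enrichment analysis.

## The method

Given a gene×cell count matrix with cluster labels and a GWAS table:

1. **Loci.** Variants with `p ≤ 5×10⁻⁸` and MAF ≥ 1% are greedily clumped
   per chromosome: the most significant unassigned variant leads a locus
   and absorbs all significant variants within 500 kb.
2. **Candidate genes.** Protein-coding genes whose body ±100 kb intersects
   a locus form the candidate set *C* (FUMA-style positional mapping,
   without the eQTL/chromatin layers).
3. **DEGs.** Counts are CP10K-log1p normalized; each gene is tested per
   cluster with a one-vs-rest two-sided Wilcoxon rank-sum test (normal
   approximation, tie and continuity corrected), BH-adjusted over all
   (gene, cluster) pairs. The DEG set *D* is every gene significant in ≥1
   cluster at FDR < 0.05 and |log₂FC| ≥ 0.25.
4. **Patterns.** Per-cluster mean profiles of *D* are z-scored per gene and
   grouped into K patterns (default 15) by deterministic k-means
   (k-means++ starts, Lloyd iterations, seeded restarts); each pattern is
   annotated with the populations whose centroid z ≥ 1.
5. **Enrichment.** With universe *U* (all expressed genes),
   the global overlap |C∩D| and each per-pattern count |C∩D∩Pₖ| are tested
   against uniform draws of matched size, with the empirical p-value

   p = (b + 1) / (n_perm + 1),  b = #{draws ≥ observed},

   co-reported with its analytic twin, the hypergeometric upper tail
   P(X ≥ observed). One shared permutation stream serves all patterns.
6. **Cross-dataset matching** (optional). Cluster marker signatures from
   two datasets (e.g., mouse and human macrophages) are compared pairwise
   by hypergeometric overlap on a harmonized symbol universe, BH-adjusted
   over all pairs.

A negative-binomial simulator (`variance = μ + φμ²`) with planted
population markers, library-size variation, a mixed low-identity
population, and a plaque-like 14-population preset makes every stage
testable end to end without patient data.

## Worked example

The bundled demo configuration simulates a plaque-like atlas (3282 cells,
14 populations, T cells ≈52%, myeloid ≈18%), plants a candidate gene set
enriched for endothelial markers, and runs the full pipeline:

```r
library(plaqmap)
cfg <- load_config(system.file("extdata", "demo_config.yaml", package = "plaqmap"))
rep <- run_all(cfg, outdir = "demo_out")
print(rep)
#> plaqmap run report (v0.1.0)
#>   cells: 3282  genes: 2000  clusters: 14
#>   gene universe: 2000  DEG set: 211  patterns: 15
#>   loci: 30  candidate genes: 30  overlap with DEGs: 13
#>   global enrichment: fold 4.13, p_perm = 0.0002, p_hyper = 3.29e-06
#>   top pattern: pattern 2 [EC9], p_perm = 0.0002
```

Thirty GWAS loci map to 30 candidate genes; 13 of them are differentially
expressed (4.1-fold more than random gene sets of the same size,
permutation p = 2×10⁻⁴), and they accumulate in a pattern annotated with
the endothelial population the candidate set was planted into — the
analysis recovers the cell type carrying the signal. Every table is written
to `demo_out/` as TSV with a JSON report, and a rerun with the same
`master_seed` reproduces all outputs byte for byte.

The same stages are scriptable from a shell via the thin CLI at
`system.file("cli", "plaqmap.R", package = "plaqmap")` (subcommands
`simulate`, `degs`, `patterns`, `map-loci`, `enrich`, `crossmap`,
`run-all`, `validate-config`).

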