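---
title: "Locus-to-cell-type enrichment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-to-cell-type enrichment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plaqmap` connects GWAS risk loci to the cell populations of a clustered
single-cell RNA-seq dataset. This vignette is the package's account of the
statistics it implements: what each stage assumes, which parameters matter
and why they default to what they do, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## The pipeline and its assumptions

The analysis treats three objects as fixed inputs: a gene×cell count
matrix with cluster labels (the clustering itself is upstream of this
package), a GWAS summary-statistics table, and a positional gene
annotation. Five stages follow.

**Locus clumping.** Variants passing genome-wide significance
(`p_thresh = 5e-8`) and a common-variant filter (`maf_min = 0.01`; a
missing MAF passes with a logged note, since many public tables omit it)
are collapsed per chromosome by greedy distance clumping: the most
significant unassigned variant becomes a lead and absorbs every
significant variant within `merge_dist = 500` kb. Distance-based clumping
stands in for LD-based clumping — no LD reference panel is bundled — so a
locus here is "a cluster of significant variants", not "a haplotype
block". Leads are chosen by smallest p, ties broken by position, which
makes the output invariant to input row order.

**Positional gene mapping.** A gene joins the candidate set when its
biotype matches (`protein_coding` by default) and its body extended by
`window = 100` kb intersects the locus span. Interval arithmetic is done
in BED coordinates (0-based, half-open); GWAS positions are 1-based and
converted only inside this stage. This is a deliberate simplification of
multi-evidence prioritization pipelines (eQTL, chromatin interaction):
positional mapping is transparent, reproducible, and monotone in the
window size. Users with an externally prioritized gene list can bypass the
stage entirely (`inputs$gene_list`).

**Differential expression.** Counts are normalized to counts-per-10,000
followed by `log1p` — the working scale throughout. Each (gene, cluster)
pair is tested with a two-sided one-vs-rest Wilcoxon rank-sum test using
the normal approximation with tie correction and a 0.5 continuity
correction; the implementation ranks each gene once and derives every
cluster's rank sum from that single ranking, which is algebraically
identical to `stats::wilcox.test(exact = FALSE, correct = TRUE)` per pair
(the test suite asserts equality to 1e-12 and checks the approximation
against the exhaustive 6-vs-6 permutation law, agreement within 0.02).
Benjamini–Hochberg adjustment runs over the *whole* (gene, cluster) table
— one error budget for the union DEG set that feeds the patterns — and a
pair is significant at `alpha = 0.05` with `|log2FC| >= 0.25`, fold
changes being computed on `expm1`-scale cluster means with a `1e-9`
pseudocount. Genes seen in fewer than `min_cells_expressing = 3` cells are
excluded from both testing and the universe; the universe definition
matters because the enrichment null samples from it, so it is explicit and
configurable rather than implicit. Rank tests assume exchangeability
within groups, not any count distribution; what they do *not* adjust for
is composition: a gene constant in counts can be genuinely shifted on the
per-cell-normalized scale when another gene dominates a cluster's library.
That is a property of CP10K scaling, not a bug, and the tests document it.

**Expression patterns.** Per-cluster mean profiles of the DEG set are
z-scored per gene (population standard deviation), making genes of
different magnitude comparable relative profiles, then grouped into
`K = 15` patterns by k-means. The clustering is deliberately pinned down:
k-means++ initialization, Lloyd iterations, `n_restarts = 50` seeded
restarts keeping the minimum within-cluster sum of squares (first winner
on ties), empty clusters re-seeded from the point farthest from its
center, assignment ties to the lowest cluster index, and final patterns
re-indexed by descending size with ties to the smallest original index.
Every one of those rules exists so that a fixed seed gives a byte-stable
result on any platform; `stats::kmeans` exposes none of them, which is why
the loop is implemented here (and cross-checked against `stats::kmeans` on
separable data, and against exhaustive enumeration of all bipartitions of
an 8-point toy, in the tests). How the reference analysis derived its
patterns is not documented anywhere we could follow; k-means on z-scored
per-cluster means is the simplest procedure consistent with a
block-structured relative-expression heatmap, and this is the largest
inferential gap in the package — hence `K`, the restart count and the
annotation threshold are all configurable, not hard-wired. A pattern is
annotated with every population whose centroid z-score reaches
`z_annot = 1.0` (about one standard deviation above that gene set's mean
profile), falling back to the argmax population so no pattern is ever
unlabeled. `K` defaults to 15 for a 14-population atlas: one pattern more
than populations leaves room for a multi-population pattern (e.g., a
smooth-muscle-plus-endothelium block) without splitting a clean one.

**Enrichment.** The candidate set C is intersected with the universe, and
the observed global overlap |C∩D| with the DEG set D is referred to
`n_perm = 10000` uniform draws of |C| genes from the universe. The
empirical p-value uses the add-one estimator `(b+1)/(n_perm+1)`, which
cannot reach zero — the smallest reportable value is `1/(n_perm+1)`. The
per-pattern test conditions on S = C∩D and draws |S|-gene sets from D,
counting them per pattern through the fixed assignment map; a single
shared permutation stream serves every pattern, so the per-pattern
p-values are mutually consistent and reproducible. Because both nulls are
uniform sampling from an explicit population, each permutation p-value has
an analytic twin — the hypergeometric upper tail — which is always
co-reported; the tests verify the two agree within Monte-Carlo error and
that the tails match exhaustive enumeration to 1e-12 on small instances.
Tests are one-sided (enrichment); depletion is visible as
`fold_enrichment < 1` but carries no p-value claim. Raw permutation
p-values are the primary output; BH adjustment across patterns is
available in `summarize_enrichment()` but is an explicitly flagged extra,
since whether the reference per-pattern values were adjusted is unknown.

**Cross-dataset matching.** Marker signatures (top 100 significant
up-regulated genes per cluster, ordered by FDR then |log2FC|) from two
datasets are compared pairwise by hypergeometric overlap on a harmonized
symbol universe — case-folding bridges the human/mouse symbol conventions
by default, and a two-column orthology table overrides it, with
many-to-many rows dropped and counted. BH runs over all query×reference
pairs jointly. The statistic behind the original mouse–human macrophage
correspondence calls is unpublished; top-N marker overlap with a
hypergeometric test is the standard realization and is stated as a
configurable contract, not a reconstruction.

## The synthetic-data generator

`simulate_counts()` draws `count ~ NB(mean = s_c · μ_g · f_gp, dispersion
= φ)`: per-gene log-normal baselines `μ_g` (meanlog −1, sdlog 1 — a
right-skewed expression distribution with a realistic share of
near-silent genes), per-cell log-normal library factors `s_c` (sdlog
0.35), and `f_gp = marker_fold` for a population's planted markers (else
1), with `variance = μ + φμ²` and `φ = 0.5` — typical droplet/plate-seq
overdispersion. A configurable fraction of cells are 50/50 mean-mixtures
of two random populations and form their own `Mixed` cluster by default,
emulating a low-identity cluster of apoptotic-like cells. The bundled
plaque preset instantiates 3282 cells in 14 populations — four T-cell
clusters totalling ≈52% of cells, a five-cluster myeloid block of ≈18.5%,
smooth muscle, two endothelial clusters, B cells, and ≈10% mixed cells.

What the generator does **not** emulate: linkage-disequilibrium structure
(GWAS fixtures plant independent variants), batch and patient effects,
doublets beyond the symmetric mixture model, UMI saturation, and
gene–gene correlation beyond the marker blocks. Passing the recovery and
calibration tests therefore shows the pipeline is correct *under its own
stated model*; it does not certify performance on real plaque data, where
marker structure is softer and clusters are imperfect.

GWAS fixtures tile genes at 600 kb spacing — deliberately wider than the
default 500 kb merge distance, so a clumped locus can never straddle a
neighbouring gene and the planted-gene list is exactly recoverable; decoy
variants are scattered at 2/Mb with p-values sampled strictly above
genome-wide significance.

## Validation studies and their sizes

The test suite and `scripts/acceptance.R` run four simulation studies,
sized so each completes in seconds to a few minutes on one core:

* **Oracle agreement** — universe 200, DEG set 50, 20 candidates, 20,000
  permutations, 10 seeds: permutation and hypergeometric p-values must
  agree within three binomial standard errors in at least 9 of 10 seeds.
* **Type-I error** — 10 simulated datasets (800 genes, 10 populations of
  40 cells, 60 markers each, fold 4 — ≈600 DEGs in 10 patterns), each
  with 20 independent *unenriched* 60-gene candidate sets: the fraction of
  pattern tests with p < 0.05 must lie in [0.03, 0.07]. Sixty candidates
  (rather than 30) keep the overlap set large enough that the discreteness
  of small hypergeometric tails does not dominate the rejection rate.
* **Power** — the same study conditions with 30 candidates at
  `enrich_frac = 0.4` planted into one population: the planted pattern
  must attain the minimum permutation p in ≥95 of 100 seeded runs.
* **DEG recovery** — 20 datasets of 1000 genes, 5 populations × 50 cells,
  10 markers each at fold 4, dispersion 0.5: mean sensitivity ≥0.90 for
  planted markers (significant, up, in their own population) with pooled
  gene-level empirical FDR ≤1.5× the nominal 0.05. FDR is assessed at the
  gene level because one-vs-rest testing makes a genuine marker of
  population *p* legitimately differential in *other* clusters too (the
  "rest" group contains *p*), so per-pair falseness is not well defined
  against the planted truth.

## Reproducibility mechanics

Every seeded operation saves and restores the session RNG state, so
results are pure functions of their seed arguments. The pipeline derives
per-stage seeds by hashing the stage name into the master seed
(`stage_seed()`), so adding a stage never perturbs another stage's
stream. Wall-clock timings are logged to the console only, never written
into result files, so a rerun under one `master_seed` reproduces every
TSV and JSON byte for byte — the determinism test asserts exactly that
with file checksums.

## Known limitations

* Positional mapping misses genes regulated at a distance; the gene-list
  bypass exists for externally prioritized sets.
* Distance clumping can merge independent signals that happen to be close
  (or split an LD block larger than `merge_dist`).
* The pattern stage's k-means is one reasonable realization among several
  (hierarchical cuts, model-based clustering); conclusions about *which*
  pattern carries a signal are conditional on that choice, which is why
  the pattern count and seeds are exposed and the procedure is fully
  deterministic.
* The Wilcoxon normal approximation is inaccurate for clusters of only a
  few cells; clusters under 3 cells are skipped outright.
* Permutation nulls sample genes uniformly — no matching on expression
  level, GC content or gene length.
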