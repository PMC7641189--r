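Package: plaqmap
Title: Mapping GWAS Risk Loci to Cell Populations of a Single-Cell Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps disease GWAS risk loci to the cell populations of a
    single-cell RNA-seq atlas, as used for coronary-artery-disease loci in
    atherosclerotic plaque. Provides distance-based clumping of genome-wide
    significant variants into loci, positional mapping of protein-coding
    candidate genes, one-vs-rest Wilcoxon differential expression across cell
    clusters, k-means grouping of differentially expressed genes into
    population-matched expression patterns, permutation and exact
    hypergeometric tests for global and per-pattern enrichment of candidate
    genes, cross-dataset cluster matching by marker-set overlap, and a
    negative-binomial single-cell count simulator with planted markers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
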