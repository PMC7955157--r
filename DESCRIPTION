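Package: altiscan
Title: Landscape-Genomics Selection Scans from Multi-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for detecting environmental adaptation in
    structured populations from genome-wide SNP genotypes. Implements the
    standard marker and sample quality-control chain (site filters, exact
    Hardy-Weinberg test, LD pruning, KING-robust relatedness filtering,
    per-SNP nucleotide diversity), Weir-Cockerham F_ST and the population
    branch statistic (PBS) with 9-SNP sliding-window summaries, a
    genotype-environment association scan producing Bayes factors in deciban
    units under a Gaussian approximation of the standardized-covariate model
    with an estimated population covariance (omega) matrix, top-quantile
    outlier-SNP selection with gene cataloguing, hypergeometric candidate
    gene-set enrichment, and principal-component summaries of environmental
    covariates and genotypes. A multi-population genotype simulator with
    planted environment-associated and branch-shifted loci provides a
    ground-truth test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    zoo,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
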