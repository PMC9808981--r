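Package: dpescan
Title: Differential Presence of Exons in Cell-Free DNA Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exon-level analysis of whole-exome cell-free DNA (liquid
    biopsy) cohorts. Counts read fragments per exon from alignments,
    filters and TMM-normalizes exon count matrices, and calls
    differentially present exons (DPE) by consensus of negative-binomial
    GLM likelihood-ratio and quasi-likelihood F tests at a strict FDR.
    Derives cross-comparison exonic signatures, explores cohorts by Ward
    clustering, PCA and leading-log-fold-change MDS, classifies samples
    with a bagged-tree random forest, performs hypergeometric gene-set
    over-representation analysis, and simulates synthetic cohorts with
    known ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    truncnorm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
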