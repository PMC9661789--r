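Package: riceeco
Title: Population-Genomic Scans of Rice Ecotype Domestication
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed nucleotide diversity and Weir-Cockerham FST scans,
    reduction-of-diversity (ROD) and composite selective-sweep detection with
    top-quantile region calling, standing/new/lost variant classification with
    allele-frequency differentiation, a mixed-model GWAS on a binary ecotype
    phenotype with an LD-pruning-derived significance threshold, and
    RPKM-ratio plus haplotype candidate-gene screening. Ships a forward
    Wright-Fisher domestication simulator (bottlenecks, selfing, planted
    sweeps, post-split mutations) so the whole pipeline is exercisable on
    synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
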