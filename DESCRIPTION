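Package: ccqtl
Title: Haplotype-Based QTL Mapping in Collaborative Cross Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for haplotype-based genetic mapping in Collaborative
    Cross (CC) recombinant inbred mouse panels: simulation of CC cohorts
    (founder mosaics, founder-descent probabilities, replicated phenotypes
    with covariates and planted QTLs), genome scans by nested-model F tests
    on founder-descent probabilities, permutation-based genome-wide
    significance thresholds, QTL calling with regional heritability and
    founder-effect deviations, merge analysis (imputing biallelic ancestral
    variants through the haplotype mosaic) for fine mapping, residual
    resampling confidence intervals for QTL location, broad-sense and
    line-mean heritability, Duncan's multiple range grouping of line means,
    and qPCR delta-delta-Ct expression-phenotype correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    car,
    vcfR,
    rtracklayer,
    GenomicRanges
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
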