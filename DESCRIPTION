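Package: sbdriver
Title: Driver Discovery from Sleeping Beauty Transposon Insertional Mutagenesis Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of Sleeping Beauty (SB) transposon
    insertional-mutagenesis screens, from per-specimen insertion-site calls to
    candidate cancer driver genes. Implements TA-dinucleotide background models
    over gene footprints, Poisson enrichment tests with discovery (FDR),
    progression and trunk (FWER) driver tiers, read-depth clonality thresholds,
    donor-chromosome local-hopping detection and censoring, activating versus
    inactivating orientation classification, fixed-margin mutual-exclusivity
    permutation tests, multi-region clonal-evolution clustering (Hamming
    distance, Ward linkage), transposon splice-fusion read detection in RNA
    data, oncoprint-style matrix export, and a synthetic-cohort simulator with
    ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rcpp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Sequencing, SomaticMutation, Software, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'clonality.R'
    'drivers.R'
    'heterogeneity.R'
    'insertion-io.R'
    'report.R'
    'sbdriver-package.R'
    'sbfusion.R'
    'simulate.R'
LinkingTo:
    Rcpp
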