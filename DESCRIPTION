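Package: mpragxe
Title: Allelic and Condition-Specific Regulatory Effects from Massively
    Parallel Reporter Assay Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of biallelic STARR-seq style massively parallel
    reporter assays (MPRA) across two environmental conditions. Estimates
    allele-specific effects (ASE) per replicate under a beta-binomial model
    anchored on the DNA plasmid-library allelic proportion, combines
    replicates by inverse-variance meta-analysis, and tests for
    genotype-environment interactions (conditional ASE) with the squared
    z-score difference statistic calibrated by genomic control. Includes a
    negative-binomial Wald test for treatment effects on target activity,
    position-weight-matrix motif scanning with proportion-test enrichment,
    interval-overlap Fisher enrichment, and a synthetic MPRA data generator
    with a full ground-truth channel for calibration and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    MASS,
    stats,
    tibble,
    utils,
    withr
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
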