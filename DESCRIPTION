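Package: pmregger
Title: Probabilistic Two-Sample Mendelian Randomization with Pleiotropy Control for TWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements PMR-Egger, a probabilistic two-sample Mendelian
    randomization method for transcriptome-wide association studies (TWAS).
    All correlated cis-SNPs of a gene are used jointly as instruments under a
    polygenic normal prior on their expression effects, while an equal
    (Egger-style) horizontal pleiotropic effect per SNP is estimated and
    controlled for. The gene-to-trait causal effect and the pleiotropic effect
    are each tested by a likelihood-ratio test, with maximum likelihood
    obtained by an expectation-maximization algorithm over p-dimensional
    sufficient statistics, so that GWAS cohorts of hundreds of thousands of
    individuals cost no more than small ones. Both individual-level and
    summary-statistics (plus LD reference panel) inputs are supported,
    together with a simulation engine for calibration and power studies, a
    per-gene TWAS scan, and evaluation utilities (genomic control factors,
    empirical-FDR power, parameter-recovery summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
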