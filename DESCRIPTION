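Package: paircn
Title: Paired Shallow Whole-Genome Copy-Number Analysis for Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for absolute copy-number analysis of paired
    diagnosis/relapse tumour cohorts profiled by shallow (~0.1x) whole-genome
    sequencing. Provides a synthetic paired-cohort generator with known ground
    truth (purity, ploidy, signature-driven segment structure, clinical labels),
    GC/mappability bias correction and penalised changepoint segmentation of
    binned read counts, grid-search purity/ploidy fitting to absolute copy
    number with quantitative QC, copy-number signature exposure quantification
    by constrained decomposition, intra-tumour heterogeneity scoring, paired
    genome subtraction with per-bin rank tests and chromosome-wise FDR control,
    ploidy-aware focal gene event calling with Fisher tests, and compositional
    differential-abundance testing of signature exposures via isometric
    log-ratio coordinates and a mixed-effects Wald test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    MASS,
    pracma,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
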