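Package: m6ascape
Title: Consensus m6A Peak Processing, Quantification, Subtyping and
    Regulator Discovery for MeRIP-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for transcriptome-wide N6-methyladenosine
    (m6A) analysis in tumor cohorts profiled by MeRIP-seq. Implements two-caller
    consensus peak processing with m6Am filtering and recurrence thresholds,
    relative m6A quantification as IP/input RPKM ratios, paired and two-condition
    differential methylation with permutation nulls, resampling consensus
    clustering for m6A-based molecular subtyping with clinical and survival
    association tests, random-forest per-prediction feature-contribution
    decomposition for ranking candidate regulator RNA-binding proteins,
    CIMS-based miCLIP single-nucleotide m6A calling with co-localization
    statistics, and GRO-seq wave-peak estimation of RNA polymerase II elongation
    rates. A synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    survival
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
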