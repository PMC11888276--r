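Package: crevip
Title: Cell-Class-Specific Gapped k-mer SVMs and Variant Impact
    Prediction for Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains cell-class-specific gapped k-mer support vector
    machines (gkm-SVM) on chromatin-accessibility peak sets and uses the
    fitted k-mer weights to produce deltaSVM-style Variant Impact
    Prediction (VIP) scores for single-nucleotide variants and indels in
    candidate cis-regulatory elements.  Includes peak-set curation
    (summit extension, universal-region removal, GC-matched negative
    sampling), an exact gapped k-mer string kernel with five-fold
    cross-validation, full 11-mer vocabulary ranking with JASPAR motif
    enrichment z-scores, in-silico saturation mutagenesis with
    motif-centered VIP profiles, correlation of predictions against
    massively parallel reporter assay (MPRA) measurements, and a
    synthetic multi-class data generator with planted motif grammars for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    kernlab,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
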