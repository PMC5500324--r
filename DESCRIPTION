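Package: pistilscreen
Title: Cross-Dataset Screening for Pistil-Specific Genes and Secreted
    Cysteine-Rich Peptides in Tomato
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification of
    tissue-specific genes from bulk RNA-seq, modelled on screens for
    pistil-specific genes expressed during fruit set in tomato. Provides
    RPKM/RPM quantification, quantile normalization, a four-stage
    cross-dataset specificity filter cascade with per-gene provenance,
    hypergeometric GO-term over-representation testing with
    Benjamini-Hochberg FDR control, a sequence-level classifier for small
    secreted cysteine-rich peptide (CRP) candidates, and a synthetic-data
    generator with planted ground truth for validating the screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
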