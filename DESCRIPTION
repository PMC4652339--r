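Package: orthozip
Title: Comparative Genomics and Expression Analysis of the bZIP
    Transcription-Factor Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for motif-based identification of
    basic leucine-zipper (bZIP) transcription factors in plant proteomes,
    InParanoid-style ortholog and in-paralog clustering with confidence
    values, orthology-distance statistics and UPGMA "orthophylogram"
    construction, and anther-expression analyses including relative
    quantification by the 2^-ddCt method, differential-expression filtering,
    probe-to-gene mapping by alignment E-values, low-temperature
    responsiveness grouping, and heterosis expression-mode classification.
    A synthetic-data module generates multi-species proteomes with known
    ortholog truth and planted bZIP domains, and replicated expression and
    qPCR cycle-threshold panels with planted fold changes and dominance
    modes, so every stage of the pipeline can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
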