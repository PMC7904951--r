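Package: ripsef
Title: RIP-Seq Target Calling and Soma-Germline Expression Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for identifying transcripts bound by an
    endoribonuclease from RIP-Seq count data and characterising its germline
    targets. Implements pseudo-counted IP/mock enrichment calling on RPM/RPKM
    abundances (longest-isoform lengths), a negative-binomial Wald test for
    two-group differential expression of gonad count tables, gene-set
    classification of bound targets into repressed (class I) and activated
    (class II) classes with chi-square binding-enrichment tests, a
    pseudo-counted soma-enrichment factor (SEF) contrasting whole-animal and
    gonad transcriptomes, transgene rescue assessment, and Oil Red O
    red-excess lipid quantification from worm micrographs. A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils,
    tools,
    multcomp,
    png
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    tiff,
    EBImage,
    jsonlite
Config/testthat/edition: 3
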