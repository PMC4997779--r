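Package: tfsilence
Title: Multi-Omic Attribution of Transcription Factor Silencing in Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for studying epigenetic silencing of
    bivalently/PRC2-marked transcription factors in cancer. Identifies
    transcription factors upregulated in a normal tissue relative to an
    embryonic stem-cell ground state, tests their preferential silencing in
    the matched cancer type against expression-matched non-housekeeping
    control genes, and attributes per-tumour silencing events to promoter
    hypermethylation, copy-number loss, or inactivating mutation, including
    mutual-exclusivity analyses and a Fisher combined-probability
    meta-analysis across cancer types. Ships a self-contained statistical
    kernel (empirical-Bayes moderated t-statistics, rank-sum and Fisher exact
    tests, Fisher's method), a recursive promoter methylation model for
    450k-style probe data, readers for the standard input formats (TSV
    matrices, SEG, minimal MAF, BED), and a seeded synthetic multi-omic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
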