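Package: damtargets
Title: Transcription-Factor Target Calling from DamID Binding and Knockdown RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for calling direct transcription-factor
    targets in a cell type of interest, modelled on DamID-seq plus bulk RNA-seq
    study designs. Implements cell-type signature-gene scoring from RPKM
    profiles, a transparent negative-binomial differential-count engine
    (median-of-ratios normalization, moderated method-of-moments dispersion,
    Wald test, Benjamini-Hochberg FDR), permutation gene-set enrichment
    analysis with a weighted running-sum statistic, DamID GATC-fragment
    differential binding with peak merging and strand-aware gene annotation,
    binding-by-expression target intersection, degenerate consensus-motif
    scanning with TSS-relative coordinates, and a seeded synthetic-data
    generator that emulates the full study structure with ground truth for
    every downstream caller.
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
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    withr
Config/testthat/edition: 3
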