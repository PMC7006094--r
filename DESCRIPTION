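Package: caddscore
Title: CADD-Style Deleteriousness Scoring of Single Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds combined annotation dependent depletion (CADD) style
    deleteriousness scores for single nucleotide variants in a non-model
    genome. Constructs a proxy-benign class of evolutionarily derived
    alleles from population allele frequencies and an inferred ancestral
    sequence, simulates a proxy-deleterious class of de novo variants from
    windowed CpG-aware substitution rates, annotates variants with
    consequence categories, conservation tracks, Grantham distances and
    DNA-shape deltas, trains an L2-regularised logistic regression to
    separate the two classes, and transforms raw scores into PHRED-like
    log-rank scores. Includes region-level Mann-Whitney analyses (codon
    positions, miRNA versus flanks, intron position, tissue-specific
    versus housekeeping gene sets) and a synthetic-genome fixture
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    Rsamtools,
    jsonlite,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    knitr
Config/testthat/edition: 3
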