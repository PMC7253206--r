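Package: cistrans
Title: Cis- and Trans-Regulatory Divergence from Allele-Specific Expression in F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting cis- and trans-regulatory divergence between
    two parental accessions from allele-specific expression (ASE) in their F1
    hybrid. Starting from reciprocal heterozygous SNP records called against
    parent-specific pseudoreferences, the package filters and aggregates
    per-allele read depths into gene-level allele count profiles, fits
    negative-binomial generalized linear models with likelihood-ratio tests
    for parental divergence, allelic imbalance (cis) and allele-by-generation
    interaction (trans), and sorts transcripts into seven categories of
    regulatory divergence. It also quantifies dominance of expression and of
    fruit morphometric traits (additive effect, dominance deviation, degree of
    dominance), analyses coexpression-network neighborhoods (betweenness
    centrality, transcription-factor enrichment), and ships a synthetic-data
    generator producing allele-specific count matrices, SNP record pairs and
    fruit measurements with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    rtracklayer,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
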