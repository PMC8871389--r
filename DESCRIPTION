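Package: aggregomics
Title: Differential Protein Aggregation, Supersaturation and Enrichment
    Analysis for Genotoxic-Stress Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy pipeline for studying stress-induced protein aggregation
    from label-free proteomics of SDS-insoluble (aggregate) and whole-cell
    lysate fractions. Implements MaxQuant proteinGroups ingestion, averaged
    downshifted-Gaussian imputation of missing-not-at-random LFQ values,
    replicate-gated differential aggregation calls with Benjamini-Hochberg
    correction, classification of the proteome into increased / decreased /
    baseline-aggregating / NIA fractions, supersaturation scoring combining
    transcript abundance with sequence aggregation propensity, simplified
    liquid-liquid phase separation propensity scoring, contingency-based
    annotation-set enrichment, figure-level rank statistics, a simplified
    negative-binomial likelihood-ratio RNA-seq differential-expression stage,
    and a ground-truth simulator for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
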