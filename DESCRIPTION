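Package: uegkit
Title: Characterizing Ubiquitously Expressed Genes from Transcriptome Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven toolkit for characterizing ubiquitously expressed
    genes (UEGs) from large collections of bulk transcriptomes. Provides
    TPM/RPKM normalization, a reference-gene quality filter, sample-wise
    quantile transformation of expression profiles into percentile ranks,
    global expression specificity at configurable detection thresholds,
    dynamic-range summaries (percentile vectors, interquartile range,
    skewness), percentile clustering of genes by distribution shape via
    affinity propagation or k-means, a five-way specificity categorization,
    selection of low-variability UEGs usable as internal reference genes,
    and an evaluation report for candidate (e.g., putative disallowed)
    genes. A synthetic compendium generator with complete truth tables
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
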