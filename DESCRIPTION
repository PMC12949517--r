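Package: hippatlas
Title: Cross-Species Hippocampal Spatial Transcriptomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-species analysis of hippocampal spatial
    transcriptomics and single-nucleus RNA-seq data: transcriptome-based
    subregion segmentation of serial sections, correlation-based registration
    of spatial cells onto reference cell types, consensus co-clustering
    homology matrices for species-specific cell-type detection, and
    positional statistics along the hippocampal longitudinal axis
    (heterogeneity, anterior/posterior preference, laminar profiles,
    permutation neighborhood enrichment, and gene-family axis scores).
    Ships a seeded multi-species synthetic-data generator with known
    taxonomy, subregion geometry and longitudinal gradients so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
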