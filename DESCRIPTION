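Package: phosphoreg
Title: Regulatory Linkage Analysis for Trimodal Single-Cell
    Protein, Chromatin, and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell experiments that jointly measure
    chromatin accessibility, intracellular antibody-derived tags (ADTs,
    including phospho-specific antibodies), and RNA. Implements ADT
    normalization with free-oligo (spiked unconjugated tag) background
    regression, staining-index benchmarking, TF-IDF/LSI chromatin
    embeddings, position-weight-matrix scanning with JASPAR-style
    relative scores, chromVAR-style per-cell motif deviation z-scores,
    ADT-to-motif rank-correlation analysis, metacell aggregation, an
    adaptive ADT-to-peak correlation procedure with motif filtering,
    peak-to-gene linkage with activating/repressive classification,
    gene-set module scores, ADT-quantile Tn5 footprinting, and
    wild-type/knockout differential accessibility with motif enrichment
    and concordance tests. Ships a synthetic trimodal data generator
    with planted TF-to-CRE-to-gene regulatory structure that serves as
    a recovery oracle for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
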