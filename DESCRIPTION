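Package: mplckit
Title: Multi-Lesion Single-Cell Tumour Analysis: CNV-Based Malignancy Calling,
    Repertoire Overlap, Mutation Statistics and Ligand-Receptor Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for single-cell studies of multifocal
    (multiple primary) lung cancer and similar multi-lesion tumour designs.
    Implements quality-control filtering of cells and genes with highly
    variable gene selection; genome-ordered copy-number inference from
    expression against a normal epithelial reference with a CNV-signal /
    CNV-R-score malignancy classifier; cell-type composition summaries
    across pathology groups; T- and B-cell receptor clonotype accounting
    with repertoire overlap coefficients; per-lesion tumour mutational
    burden and variant allele frequency statistics; and filtered
    ligand-receptor interaction counting with a cluster-label permutation
    test. A seeded synthetic-data module plants known copy-number segments,
    shared variants and shared clonotypes so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
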