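Package: repairscape
Title: Cas9 Mutational Outcome Profiles in DNA-Repair-Deficient Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR-Cas9 editing outcome screens across DNA
    repair gene knockout cell lines. Provides a canonical algebra for indel
    outcomes (left-aligned representation, deduplication, microhomology,
    ten-category classification, insertion templating, deletion directionality),
    a synthetic screen generator with planted and recoverable structure,
    read-count filtering and pooling into outcome profiles, knockout log2
    fold-change profiling with bootstrap summaries of 1 bp insertion biases,
    exponential microhomology-decay regression, spectral embedding and
    clustering of knockout response profiles, and per-cell-line predictive
    models of outcome distributions trained by Kullback-Leibler-minimising
    softmax regression over binary sequence features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
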