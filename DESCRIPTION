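Package: compendex
Title: Expression Compendium Storage, Co-Expression Prediction, and
    Compressed Signature Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and querying large uniformly processed
    RNA-seq expression compendia. Provides an HDF5-backed compendium
    container with per-sample metadata search and per-series count export;
    quantile normalization, log2 transformation and per-gene z-scoring;
    chunked gene-gene Pearson correlation with sample subsampling;
    guilt-by-association prediction of gene function and protein-protein
    interactions scored by mean co-expression and benchmarked with
    membership AUC (Mann-Whitney/trapezoidal); Johnson-Lindenstrauss
    random projection of the compendium for real-time up/down gene
    signature similarity search; and a synthetic compendium generator
    with planted gene modules and sample clusters so every component is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rhdf5,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
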