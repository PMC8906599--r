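Package: methodsminer
Title: Topic Modelling and Boilerplate Detection for Statistical Methods Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining corpora of statistical-methods sections from
    journal articles and clinical-trial registrations. Normalizes section
    text (symbol verbalization, reference and formatting removal, stop-word
    filtering with a retain list, statistical-term standardization),
    discovers topics with tf-idf weighting and non-negative matrix
    factorization, and quantifies boilerplate ("cut-and-paste") text with an
    asymmetric Jaccard containment score accelerated by MinHash
    locality-sensitive hashing. Includes a synthetic-corpus generator that
    plants boilerplate templates at known containment levels with full
    ground truth, and a command-line pipeline for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
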