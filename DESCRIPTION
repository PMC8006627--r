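Package: deidr
Title: De-Identification of Spanish Clinical Free Text with BiLSTM-CRF
    Taggers and Surrogate Substitution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects protected health information in Spanish-language
    medical free-text reports (radiology-style) with bidirectional
    LSTM-CRF sequence taggers over seven entity categories (section
    headers, person names, addresses, populated places, identifying
    numbers, dates, healthcare institutions), and replaces detected
    entities with category-matched synthetic surrogates sampled from
    weighted gazetteers, so residual detection misses cannot be told
    apart from substituted text.  Includes CoNLL-2002-style and BRAT
    standoff corpus readers and writers, gazetteer-based pre-annotation,
    a synthetic-corpus generator emulating the structural profiles of
    regional radiology reports, token-level per-entity and global
    de-identification metrics, and a command-line interface.
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
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
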