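Package: drugchatter
Title: Mining Drug-Related Social-Media Chatter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for pharmacovigilance text mining of
    drug-related social-media chatter. Implements phonetic misspelling-variant
    generation for recall-oriented keyword collection, corpus filtering and
    summary statistics against a drug lexicon, interpolated Kneser-Ney n-gram
    language models (orders 2-4) with ARPA-format interchange, skip-gram word
    embeddings with negative sampling, cosine-similarity drug-adverse-reaction
    association signals, language-model scoring of health-related text, and a
    synthetic tweet-corpus generator with planted structure so the whole
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
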