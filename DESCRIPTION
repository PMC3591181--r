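Package: nanoner
Title: Named Entity Recognition for Nanotoxicology Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for recognizing nanotoxicology-related entities
    (nanoparticles, routes of exposure, toxic effects, and targets) in
    sentences from the scientific literature. Provides an inline-tag
    annotated-corpus format with a chemical-formula-aware tokenizer, BIO
    sequence encoding, a linear-chain conditional random field trained by
    penalized maximum likelihood, entity-level and token-level evaluation
    metrics with k-fold cross-validation, a dictionary plus TF-IDF
    baseline annotator, and a seeded synthetic corpus generator for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
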