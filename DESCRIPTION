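Package: clstm
Title: Contextual BiLSTM-CRF Sequence Labeling for Biomedical Named Entity
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Named entity recognition for biomedical text with a contextual
    long short-term memory network (CLSTM): character- and word-level
    bidirectional LSTMs whose inputs are n-gram context windows of
    neighboring embeddings, topped by a linear-chain conditional random
    field. Includes IOB tagging utilities, CoNLL and PubTator corpus
    readers and writers, strict, partial and token-level evaluation,
    a deterministic synthetic-corpus generator for end-to-end testing,
    and a training harness with multi-trial robustness summaries and
    cross-corpus evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    igraph,
    withr
Config/testthat/edition: 3
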