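Package: ddilstm
Title: Dependency-Based Multichannel Bi-LSTM for Drug-Drug Interaction Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extracting drug-drug interactions (DDI) from annotated
    biomedical sentences. Implements the full pipeline around a three-channel
    bidirectional peephole LSTM relation classifier: reading the DDIExtraction
    2013 XML dialect and CoNLL-U dependency parses, drug blinding, rule-based
    negative-instance filtering, relative-distance and dependency-depth
    features with depth-first and breadth-first tree linearization,
    imbalance-aware training (per-epoch negative undersampling and repeated
    minority oversampling, Adam with gradient clipping, L2 and parameter
    averaging), DDIExtraction-2013-style evaluation, and a synthetic corpus
    generator with planted, learnable class signals for desk-scale testing.
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
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
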