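Package: lncmir
Title: Sequence-Based Prediction of lncRNA-miRNA Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lncRNA-miRNA interactions from nucleotide sequence alone.
    Each RNA is encoded by four hybrid feature categories (k-mer spectrum,
    composition/transition/distribution descriptor, a PV-DM document embedding
    of 3-mer tokens, and an attributed random-walk embedding of a linear
    neighborhood similarity graph), fused into a fixed 20x20x4 histogram
    tensor, and classified by a twin-tower convolutional network with a
    sigmoid output. Includes negative-pair sampling, stratified k-fold
    cross-validation, the usual confusion-table metrics plus rank-based AUC,
    and a synthetic corpus generator that plants a miRNA seed-complement
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
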