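Package: lpiembed
Title: Heterogeneous Network Embedding for lncRNA-Protein Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts lncRNA-protein interactions by embedding typed
    heterogeneous networks. Known interactions are combined with
    lncRNA-lncRNA and protein-protein similarity edges (Jaccard over
    shared interaction partners, or sequence-alignment e-values) into
    two heterogeneous networks; nodes are embedded with meta-path
    constrained random walks and skip-gram; candidate pairs are scored
    with an RBF-kernel support vector machine. Includes three
    negative-sampling strategies (random pairing, subcellular
    localization incompatibility, shortest-path network distance), a
    full evaluation suite (precision, recall, specificity, accuracy,
    Matthews correlation, F1, ROC/AUC), and a planted-block synthetic
    benchmark generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    e1071,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
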