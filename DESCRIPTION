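Package: duplexgnn
Title: Graph Neural Network Classification of miRNA-mRNA Duplexes from
    Word-Embedded Nucleotide Triplets
Version: 0.1.0
Authors@R:
    person("Duplex", "GNN Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA target sites by encoding a miRNA-mRNA duplex as a
    graph of word2vec-embedded nucleotide triplets and classifying it with a
    graph neural network. Provides CBOW word embeddings fitted per corpus on
    training data only, duplex graph construction (chain plus aligned cross
    edges), three node-embedding layer families (spectral convolution,
    sample-and-aggregate, attention), global pooling readouts, a fully
    connected softmax head, the full training and multi-replicate evaluation
    protocol (Adam, plateau learning-rate reduction, early stopping, balanced
    accuracy / precision / recall with confidence intervals), a planted-signal
    synthetic duplex generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
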