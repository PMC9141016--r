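Package: splicecnn
Title: Convolutional Splice-Site Prediction in Genomic Sequences
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A trainable toolkit for donor/acceptor splice-site prediction in
    eukaryotic genomic sequences. Builds three-class (donor, acceptor, other)
    labeled window datasets from annotated gene sequences, trains a
    one-dimensional convolutional neural network with batch normalization and
    L1-regularized filters, scans whole sequences per-nucleotide with a
    sliding window to produce probability tracks, and evaluates predictions
    with ranked-retrieval statistics (top-k and top-percent accuracy) and
    per-gene false-positive percentages. Includes a synthetic-genome
    generator that plants position-weight-matrix splice signals around
    canonical GT/AG dinucleotides so the full pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
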