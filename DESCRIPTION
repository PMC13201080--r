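Package: olann
Title: Long-Read Overlap Detection via Weighted k-mer Features, Sparse
    Random Projection and Nearest-Neighbour Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects candidate overlaps between long sequencing reads by
    encoding each read (and its reverse complement) as a sparse vector over a
    sampled canonical k-mer alphabet, down-weighting repetitive k-mers with an
    inverse-document-frequency transform, embedding reads with a fused sparse
    random projection, and retrieving each read's top-k nearest neighbours
    under cosine distance with either an exact search or a native NN-descent
    approximate search. Includes a synthetic long-read simulator with
    ground-truth placement, reference overlap-graph construction from truth
    tables or PAF alignments, and the error-rate, mean-overlap-size,
    correct-candidate-degree and connected-component metrics used to score
    overlap graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Matrix,
    Rcpp,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
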