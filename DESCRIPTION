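Package: scTripletClust
Title: Single-Cell RNA-Seq Clustering with Graph Attention Autoencoders
    and High-Order Triplet Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single-cell RNA sequencing data by learning cell
    embeddings with a multi-head graph-attentional autoencoder on a
    denoised k-nearest-neighbour cell similarity graph, sharpening the
    embeddings with a triplet loss whose positive pairs come from
    high-order (shortest-path) neighbours of the graph, and fusing the
    result with self-optimizing (deep embedded) clustering.  Includes
    quality-control filtering, normalization and dimensionality
    reduction for raw count matrices, a negative-binomial/dropout
    simulator for cluster-structured counts, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
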