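Package: morphograph
Title: Morphotype Detection in Morphospace Graphs with Graph Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised delimitation of morphotypes from specimen-by-trait
    tables. Builds a k-nearest-neighbour morphospace graph from allometrically
    corrected linear measurements and scale counts, embeds specimens with a
    graph-convolutional autoencoder trained on weighted binary cross-entropy,
    partitions the reconstructed adjacency with Louvain modularity
    maximisation, and surrounds the core with latent-dimension selection
    (edge AUC, trustworthiness, distance correlation), SHAP-based per-cluster
    trait diagnosis, a PCA/k-means linear baseline, and a stratified
    variable-subset stability analysis. Includes a planted-morphotype
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    cluster,
    igraph,
    jsonlite,
    methods,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
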