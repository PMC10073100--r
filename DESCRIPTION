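Package: dmviz
Title: Structure-Preserving Deep Manifold Visualization of Single-Cell
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parametric dimensionality reduction for bulk and single-cell
    expression matrices. A two-stage neural network embeds cells into a 2- or
    3-dimensional Euclidean or hyperbolic (Poincare ball or Lorentz model)
    latent space while preserving the geometric structure of the data, using a
    fuzzy cross-entropy loss between a learned structure graph and the
    visualization graph. Multilevel categorical batch effects (patient,
    disease, location, ...) are corrected end-to-end through a prior batch
    graph added to the visualization similarities; the encoder itself never
    sees the batch vector, so trained models can map new, possibly
    heterogeneous-gene, datasets onto a reference embedding. Includes the
    preprocessing pipeline (library-size normalization, log transform,
    standardization, PCA), exact hyperbolic geometry primitives, co-ranking
    quality criteria, k-NN label transfer and batch-mixing diagnostics, and a
    synthetic count-data generator with cluster, branching-trajectory and
    multilevel batch-effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    data.table
Config/testthat/edition: 3
LinkingTo: Rcpp
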