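Package: klsnet
Title: Individual Brain Metabolic Connectivity Networks from Intensity
    Distribution Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs single-subject brain metabolic connectivity networks
    from parcellated intensity images. Per-parcel voxel intensity
    distributions are estimated by kernel density estimation with a
    diffusion-based (Botev) bandwidth on a standardized grid, edge weights
    are derived from the symmetric Kullback-Leibler divergence between
    parcel densities (KLS = exp(-DKL)), and the resulting fully weighted
    undirected graphs are characterized by strength, characteristic path
    length, weighted clustering, local efficiency, betweenness and hub
    scores. Includes linear/quadratic age regression with nested-model F
    selection, a phantom-cohort generator for validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
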