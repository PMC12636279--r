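Package: scovnet
Title: Structural Covariance Network Analysis of Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group-level structural covariance network (SCN) analysis of
    regional gray-matter volumes. Builds one weighted, nonnegative
    correlation network per subject group from TIV-normalized region-of-
    interest volumes (Pearson or covariate-adjusted partial Pearson, with
    negative edges truncated to zero), computes weighted nodal metrics
    (strength, normalized betweenness centrality, Onnela geometric-mean
    clustering) and global small-world indices (gamma, lambda, sigma)
    against ensembles of degree-preserving rewired surrogate networks,
    and compares nodal metrics between groups with permutation tests and
    Benjamini-Hochberg false discovery rate correction. Includes a
    multivariate-Gaussian cohort simulator with block-structured
    correlation targets for validation, covariate-adjusted regional
    statistics (ANCOVA, partial Spearman), and an end-to-end pipeline
    driver with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
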