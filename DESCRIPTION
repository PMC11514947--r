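Package: histomix
Title: Histology-Integrated Bayesian Spatial Domain Detection for
    Spatially Resolved Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@histomix.org",
           role = c("aut", "cre"))
Description: Identifies histology-based spatial domains in spatially
    resolved transcriptomics (SRT) data by integrating three profiles: a
    low-dimensional molecular profile (principal components of normalized
    expression), an image profile (cell-type abundances from
    AI-classified nuclei in the matched histology image), and a
    geospatial profile (the spot adjacency graph). Stage I fits a
    Bayesian normal-multinomial finite mixture model with a Markov
    random field prior by Gibbs sampling, yielding spatial domain labels
    with uncertainty, domain-level cell-type compositions with credible
    intervals, interactive zones (ambiguous boundary regions), and an
    integrated completed likelihood (ICL) criterion for choosing the
    number of domains. Stage II detects domain-specific differentially
    expressed genes (spaDEGs) with a negative binomial regression on
    domain membership, with Benjamini-Hochberg false discovery rate
    control, plus per-spot expression richness and Moran's I
    diagnostics. A synthetic data generator reproduces the full
    generative model for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
biocViews: Transcriptomics, Spatial, Clustering, Bayesian,
    DifferentialExpression, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
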