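Package: hidalgoid
Title: Heterogeneous Intrinsic Dimension Estimation for Country-Level
    Time-Series Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the intrinsic dimension (ID) of multi-country
    time-series panels with a Bayesian mixture of Pareto likelihoods on
    nearest-neighbour distance ratios (the Hidalgo model), fitted by a
    Gibbs sampler with a neighbourhood-augmented likelihood.  Includes
    panel preprocessing (missing-data and population filters, linear
    imputation, pooled z-scoring, temporal stratification), TWO-NN
    maximum-likelihood ID estimation, label-switching-aware
    post-processing via the posterior co-clustering matrix and Variation
    of Information partition estimation, Moran's I spatial
    autocorrelation with permutation inference, and synthetic-data
    generators for multi-manifold point clouds and spatially structured
    country panels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
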