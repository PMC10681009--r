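Package: spatialith
Title: Spatial Tumour Growth Simulation and Intra-Tumour Heterogeneity
    Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of tumour expansion on a 2D or 3D
    lattice under a continuous push rate spanning surface growth (p = 0)
    to exponential growth (p = 1), with neutral Poisson mutation
    accumulation at every cell division.  Includes the downstream
    measurement stack: random and centre/margin square (cube) spatial
    sampling, Jaccard-index intra-tumour heterogeneity as a function of
    sampling distance, cumulative variant-allele-frequency curves,
    effective mutation-rate inference by linear regression on the 1/f
    spectrum, and a Kolmogorov-Smirnov-style linearity distance.  A
    generic multi-region biopsy-table mode applies the same heterogeneity
    metrics to sample-by-mutation presence tables with per-sample
    coordinates, and a fixture generator emulates such data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
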