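Package: esfrich
Title: Eigenvector Spatial Filtering Models for Gridded Species Richness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial modelling workflow for gridded tree species richness
    estimated from forest-inventory plot samples. Provides fixed-size
    bootstrap richness estimation, derivation of standard bioclimatic
    predictor variables from monthly climate series, Poisson LASSO
    variable selection with ten-fold cross-validation and the
    one-standard-error rule, Poisson log-link generalized linear models
    fitted by iteratively reweighted least squares, eigenvector spatial
    filtering on binary contiguity lattices with stepwise AIC eigenvector
    selection, and model diagnostics (Moran's I with z-scores, percent
    deviance explained, variance inflation factors, paired Wilcoxon
    signed-rank tests). A synthetic-data generator produces masked
    lattices, spatially autocorrelated environmental fields and
    plot-level species occurrence data so the whole pipeline is testable
    without raster downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    ape
Config/testthat/edition: 3
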