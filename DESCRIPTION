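Package: virtualsdm
Title: Virtual Species Experiments on Collinearity in Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for measuring how collinearity among
    environmental predictors affects species distribution models (SDMs).
    Generates spatially autocorrelated, strongly collinear synthetic
    environmental raster stacks (or reads real ones as ESRI ASCII grids),
    defines virtual species as Gaussian niches, projects their "true" ranges
    with a stochastic colonization-extinction cellular automaton, samples
    occurrence and background points, fits envelope, Mahalanobis-distance and
    presence-background learners on raw versus PCA-derived predictor sets, and
    evaluates the resulting binary maps (TSS, omission and commission rates,
    range-size recovery) in a reproducible factorial experiment with ANCOVA,
    model-stability and range-size regression summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    kernlab,
    MASS,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
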