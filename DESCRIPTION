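Package: toolnet
Title: Decoding and Effective Connectivity Analysis of Pantomimed Tool-Use fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a 2x2 delayed-pantomime
    fMRI experiment (grasp-to-move vs grasp-to-use with scissors or axe).
    Provides a synthetic BOLD generator for region-of-interest voxel time
    series with controllable action and goal encoding, trial-wise GLM
    beta-series estimation, shrinkage linear discriminant decoding with
    leave-one-run-out cross-validation (including cross-tool goal
    cross-decoding), group-level inference with Benjamini-Yekutieli false
    discovery rate control, and a three-node dynamic causal modelling engine
    (bilinear neural dynamics, balloon-Windkessel haemodynamics, Laplace
    model evidence, random-effects Bayesian model selection with exceedance
    probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
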