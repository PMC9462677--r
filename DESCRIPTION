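Package: spinefe
Title: Subject-Specific Spine-Segment Finite-Element Models Validated
    Against Full-Field Surface Displacements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds heterogeneous linear-elastic tetrahedral finite-element
    models of lumbar spine segments from calibrated quantitative computed
    tomography (QCT) density fields, drives them with rigid-body boundary
    conditions extracted from marker trajectories by the Kabsch (SVD)
    method, calibrates a homogeneous intervertebral-disc modulus to an
    experimental force target by root finding, and validates predicted
    vertebral surface displacements against digital-image-correlation
    (DIC) style point-cloud measurements using rigid registration,
    spherical averaging, Cook's-distance outlier screening and
    per-component regression metrics. Includes a synthetic two-vertebra
    phantom generator so the full pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RANN,
    deldir,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
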