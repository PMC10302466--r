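Package: pointrdf
Title: Single-Snapshot Prediction of Liquid Radial Distribution Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts the time-averaged radial distribution function of a
    homogeneous liquid from a single molecular configuration using a
    permutation-invariant point-cloud neural network fused with
    thermodynamic state scalars. Includes a compact Lennard-Jones molecular
    dynamics engine for generating labelled liquid trajectories, readers
    and writers for LAMMPS text dumps and extended XYZ, partial radial
    distribution function estimation with error metrics, and a seeded
    training and evaluation harness that compares the surrogate against the
    direct single-snapshot molecular dynamics baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
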