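Package: oculometry
Title: Ocular MRI Segmentation, 3D Eye Biometry, and Refractive-Error Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for population ocular MRI studies: a
    synthetic orbital-MRI phantom generator with ground-truth label maps and
    emulated optical biometry; automated six-region eye segmentation combining
    multi-atlas label fusion with a random-forest voxel classifier on 48
    Gaussian scale-space features; 3D anatomic-axis biometry (axial length,
    posterior segment length, height, width, compartment volumes) with
    oblate/prolate sphericity classification; and the cohort statistics that
    relate eye shape to spherical-equivalent refractive error (Pearson
    correlation, ANOVA and chi-square group comparisons, restricted cubic
    spline regression, Bland-Altman method comparison, and report tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
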