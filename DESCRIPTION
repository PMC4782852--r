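Package: shagginess
Title: Shagginess Scoring of Vessel Lumina from 3D CT Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the irregularity ("shagginess") of a vessel lumen from a
    3D CT-derived segmentation. A central luminal line is extracted from a binary
    lumen mask, cross-sections are resampled perpendicular to it (multiplanar
    reconstruction), and each cross-sectional contour is compared against the
    circle whose diameter equals the mean of 180 through-center diameter
    measurements: the ratio C of contour length to that circle's circumference
    yields a per-slice irregularity (C - 1) x 100, and the shagginess score is
    the mean over a landmark-delimited arc-length range. Includes a synthetic
    vessel phantom generator with analytically known per-slice C for validation,
    NIfTI input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
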