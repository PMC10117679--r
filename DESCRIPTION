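Package: octnorm
Title: Murine Retinal OCT Thickness Quantification and Normative Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal layer thickness from volumetric
    spectral-domain optical coherence tomography (OCT) scans of the mouse
    retina. Provides a synthetic layered-retina phantom generator with known
    ground-truth boundaries, a compact fully convolutional encoder-decoder
    for per-sample layer classification, a monotone dynamic-programming
    projection from class maps to ordered boundary surfaces, en-face
    thickness mapping with three-criterion segmentation quality control and
    region-of-interest (B1-B9) block summaries, normative database
    construction with kernel-density summaries and per-subject abnormality
    probabilities, and the longitudinal statistical battery used for
    group and age comparisons (normality-gated Welch/Mann-Whitney tests
    with Bonferroni correction, one- and two-way repeated-measures ANOVA,
    Friedman tests, and Tukey-Kramer post-hoc comparisons).
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
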