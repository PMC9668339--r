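Package: navgam
Title: Penalized Poisson Encoding Models for Closed-Loop Virtual Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits penalized Poisson generalized additive models (P-GAMs) to
    spike trains recorded during closed-loop virtual navigation ("firefly")
    tasks. Tuning functions for continuous task variables are B-splines with
    curvature penalties, discrete events and unit-to-unit coupling enter
    through causal temporal filters, and local field potential phases enter
    as periodic regressors. Includes model-quality metrics (Poisson
    pseudo-R-squared, mutual information, discrimination index), behavioral
    analyses (bias slopes, gaze prediction, target-tracking index),
    population clustering of tuning profiles, coupling-network analyses, and
    a synthetic firefly-session generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    mclust,
    withr
Config/testthat/edition: 3
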