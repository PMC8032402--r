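Package: vestuning
Title: Spatiotemporal Tuning Analysis of Self-Motion Responsive Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize single-neuron tuning to three-dimensional
    self-motion (translation and rotation) from trial-resolved spike trains.
    Implements the 26-direction stimulus geometry and Gaussian-velocity motion
    kinematics, peristimulus time histograms with sliding-window rate
    statistics, temporal- and spatial-tuning screens (rank-sum run criterion,
    per-window ANOVA, peak counting), the direction discrimination index (DDI)
    with a permutation test, vector-sum preferred directions with a spherical
    uniformity test, and a rectified spatiotemporal receptive-field model with
    velocity/acceleration (VA) and position/velocity/acceleration/jerk (PVAJ)
    temporal kernels fitted by multi-start constrained least squares and
    compared by BIC and the BIC difference index. An inhomogeneous-Poisson
    simulator generates populations from ground-truth model parameters so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    generics,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
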