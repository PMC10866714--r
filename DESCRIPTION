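Package: shrscr
Title: Single-Cell SHR/SCR Trajectory Analysis and Division-Plane Decision Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-cell SHORT-ROOT (SHR) and
    SCARECROW (SCR) fluorescence trajectories from Arabidopsis root
    meristems. Provides trajectory ingestion and preprocessing (ratio
    smoothing, quantile normalization, population averaging, cell-cycle
    segmentation), simulation and least-squares comparison of candidate
    ODE models of SCR regulation by SHR (a reduced bistable SHR-SCR-RBR
    network and three monostable alternatives) by adjusted R-squared,
    fixed-point and bistability analysis with one-at-a-time parameter
    scans, threshold classifiers of formative versus proliferative
    division restricted to nuclear-size windows with exact binomial and
    Mann-Whitney statistics, dynamic-feature extraction with a simple
    cross-validated classifier, and a ground-truth synthetic trajectory
    generator so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
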