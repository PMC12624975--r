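Package: arraystrain
Title: Micromotion Tissue Strain and Recording Performance of Utah-Style
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finite-element prediction of micromotion-induced strain in
    cortical tissue surrounding bed-of-needles ("Utah") microelectrode
    arrays, together with the electrophysiology metric pipeline used to
    relate strain to device performance. Builds parametric array and
    tissue geometries, meshes them with quadratic tetrahedra refined at
    the shank tips, solves the static nonlinear boundary-value problem
    with a one-term Ogden tissue model, and summarizes von Mises strain
    in 50 micrometre regions of interest at each electrode tip. A
    synthetic-recording generator with strain-linked ground truth feeds
    the metric pipeline (impedance screening, bandpass filtering,
    threshold-crossing snippets, peak-to-peak voltage, noise floor,
    signal-to-noise ratio, envelope multi-unit activity, neighbor
    correlations) and the rank-based statistical layer (Spearman
    correlation, Kruskal-Wallis with Dunn post-hoc, one-way ANOVA with
    Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
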