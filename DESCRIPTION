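Package: costnet
Title: Cost-Integrated Graph Analysis of Wavelet Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds resting-state functional brain networks from regional
    BOLD time series via maximum-overlap discrete wavelet transform (MODWT)
    correlations, soft-thresholds them into weighted graphs, and computes
    cost-integrated graph-theoretical topology (nodal degree, nodal/global/
    local efficiency) by Monte-Carlo averaging over thresholded wiring
    costs. Includes population-level mean statistical parametric networks
    (edge z-scores), probability-weighted regional extraction of BOLD and
    fractional-anisotropy values from probabilistic label volumes, and
    per-region general linear model association of topology with
    dimensional trait scores, with Benjamini-Hochberg false discovery rate
    control. A synthetic-cohort generator with band-limited modular BOLD
    covariance, realistic phenotype correlation structure and injectable
    trait effects makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    RNifti
Config/testthat/edition: 3
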