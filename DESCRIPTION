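Package: rnvgphase
Title: Phase Analysis of Gated Blood-Pool Ventriculography for
    Cardiotoxicity Risk Stratification
Version: 0.1.0
Authors@R:
    person("RNVG", "Phase Tools", email = "rnvgphase@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying left-ventricular dyssynchrony from gated
    planar radionuclide ventriculography (RNVG/MUGA). Extracts first-harmonic
    Fourier phase and amplitude images from gated frame stacks, computes
    approximate entropy over a serpentine pixel series together with
    synchrony, phase-histogram entropy and phase SD, supports tolerance
    (m, r) optimization with flip-point detection on simulated phase images,
    simulates phase images, gated studies and two-group patient cohorts with
    serial ejection fractions, and runs the normality-gated univariate,
    Hotelling T-squared, logistic-regression and cross-validated classifier
    statistics used for cancer-therapy-related cardiac dysfunction risk
    stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
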