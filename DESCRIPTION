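Package: mmdcm
Title: Multimodal Dynamic Causal Modelling of Neurovascular Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a canonical-microcircuit neural mass model to event-related
    electrophysiological (M/EEG) data, derives condition-specific neuronal
    drive functions from the posterior, and uses them to drive a factorial
    space of neurovascular-coupling and Balloon haemodynamic models fitted to
    region-wise fMRI time series. Model inversion uses variational Laplace
    (a free-energy bound on log evidence); hypotheses about the origin of the
    BOLD response are adjudicated by Bayesian model comparison, family-wise
    comparison and Bayesian model reduction. Includes a synthetic-data
    generator for roving-oddball style multimodal designs so the full
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
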