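Package: canheart
Title: Cross-Spectral Dynamic Causal Modelling of the Central Autonomic Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of resting-state effective connectivity among central
    autonomic network regions from BOLD time series, using a cross-spectral
    dynamic causal model (linear stochastic neuronal dynamics, Balloon
    hemodynamics, power-law noise) inverted by variational Laplace, followed by
    hierarchical parametric-empirical-Bayes group analysis with Bayesian model
    reduction. Includes motion quality control by framewise displacement,
    mean heart-rate extraction from photoplethysmography, volume-of-interest
    extraction from NIfTI images, and a synthetic cohort generator providing a
    known-truth test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
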