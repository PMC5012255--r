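Package: qcmclot
Title: Clot-Formation Analysis for Quartz Crystal Microbalance Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for blood-plasma coagulation monitored on a
    quartz crystal microbalance (QCM). Fits Lorentzian resonance peaks to
    conductance spectra to track resonant frequency and half bandwidth,
    extracts clot-formation kinetic parameters (clotting time R-QCM, maximum
    rate of clot formation MRCF and its time TMRCF, maximum response),
    computes the effective-elasticity / effective-mass viscoelastic model and
    its rigidity factor, and quantifies fibrin-network scanning electron
    microscopy images (porosity, fibre density and fibre diameter) by
    radially averaged Fourier power spectra. Includes seeded synthetic-data
    generators with closed-form ground truth for every input the pipeline
    reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    png,
    readr,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
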