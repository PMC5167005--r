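Package: nirspine
Title: Event-Related fNIRS Analysis of Mechanosensory Stimulation of the Lower Back
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous-wave functional near-infrared
    spectroscopy (fNIRS) recordings acquired during painful and nonpainful
    mechanical stimulation of the lumbar spine: conversion of two-wavelength
    optical densities to hemoglobin concentration changes via the modified
    Beer-Lambert law with an age-dependent differential pathlength factor,
    Savitzky-Golay band-pass filtering, event segmentation with per-segment
    detrending and pre-stimulus median baselining, short-separation regression
    against scalp channels, median block and grand averaging, two-track
    nonparametric group statistics (Friedman, Wilcoxon signed-rank) with
    Benjamini-Hochberg false-discovery-rate control, habituation/sensitization
    trend screening, and stimulus-locked heart-rate windowing. Includes a
    synthetic-data generator that emulates the study design (three stimulus
    conditions over two cortical regions of interest with a condition-dependent
    superficial scalp component and physiological nuisance signals) so that
    every stage is verifiable by parameter recovery and null calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
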