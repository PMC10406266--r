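Package: mreeg
Title: Artifact Reduction and Evaluation for EEG Recorded During fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, correction and evaluation tools for EEG acquired
    simultaneously with fMRI. Generates synthetic EEG-fMRI sessions with known
    ground truth (imaging/gradient, ballistocardiogram, helium-pump and motion
    artifacts, carbon-wire-loop reference channels, ECG and task-locked neural
    activity), implements the standard artifact-reduction procedures (average
    artifact subtraction, optimal-basis-set fitting, carbon-wire-loop
    regression), the spectral and evoked-potential feature-extraction
    procedures used to evaluate them (Welch band power, summary-channel
    selection, VEP difference waves, RMS-ratio SNR), and hierarchical Bayesian
    regression models with rank-normalized convergence diagnostics for
    comparing correction methods. Reads and writes BrainVision recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    yaml,
    rjags
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
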