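Package: stressEEG
Title: EEG-Based Driver Stress Classification and Frontal Alpha Asymmetry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-channel EEG studies of
    driver stress. Generates stress-labelled synthetic EEG cohorts with
    calibrated frontal-pole alpha asymmetry, preprocesses recordings
    (zero-phase band-pass filtering, re-referencing, amplitude-threshold
    artifact rejection, epoch segmentation), extracts time-domain moment
    features and Welch power-spectral-density band power over five scalp
    regions, trains and compares six stress-state classifiers headlined by a
    genetic-algorithm-optimized backpropagation neural network, and analyses
    the Fp1-Fp2 alpha asymmetry index, its Spearman rank correlation with
    ordinal stress level (with exact permutation p-values), and the effect of
    music interventions on stress as scored by the trained classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    class,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
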