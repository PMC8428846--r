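Package: pawkit
Title: Millisecond-Timescale Quantification of Paw Withdrawal and Whole-Body Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying optogenetically evoked somatosensory
    behavior from high-speed video. Detects paw-withdrawal events from
    frustrated-total-internal-reflection (FTIR) contact signals (threshold
    crossing at five baseline standard deviations, 20-80% rise times,
    response-extent classification, per-pixel latency maps), computes
    binarized whole-body motion energy and global response bouts, cleans
    markerless pose tracks and derives kinematics (movement-onset latencies,
    displacements, paw-nose distances, head yaw), and implements the
    accompanying statistics: pose PCA with trajectory direction statistics,
    a balanced hierarchical (mouse-then-trial) bootstrap, the probability
    sum rule for pulse trains, pulse-matched latencies, Friedman/Dunn
    testing and regression fits. A synthetic-trial generator with known
    ground truth closes the testing loop for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
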