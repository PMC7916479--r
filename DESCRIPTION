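Package: ssvepkit
Title: Decoding and Evaluation Toolkit for Wearable SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, decoding and evaluation for 12-target
    steady-state visual evoked potential (SSVEP) brain-computer interfaces
    recorded with wearable wet- and dry-electrode headbands. Provides a
    synthetic multichannel EEG generator with the joint frequency-phase
    modulated stimulus design, event-locked epoch extraction and
    downsampling, filter-bank canonical correlation analysis (FBCCA) and
    filter-bank task-related component analysis (FBTRCA) classifiers, a
    cross-electrode template-transfer classifier, and evaluation utilities:
    information transfer rate, narrowband spectral signal-to-noise ratio,
    filter-bank weight grid search, and group-level statistics. Reads and
    writes the per-subject 5-D epoch record format used by open wearable
    SSVEP datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
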