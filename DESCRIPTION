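Package: psinet
Title: Phase-Synchronization Brain Networks from Epoched EEG
Version: 0.1.0
Authors@R:
    person("Alex", "Chen", email = "alex.chen@example.org",
           role = c("aut", "cre"))
Description: Builds weighted functional brain networks from epoched
    multichannel EEG via Hilbert-transform instantaneous phase and the
    mean phase coherence (phase-synchronization index), characterizes
    them with weighted small-world graph metrics normalized against
    degree-preserving rewired null networks, and runs the associated
    group statistics (mixed-design ANOVA, t-contrasts, ROI node-degree
    summaries) across a network-density sweep. Includes a synthetic
    coupled-oscillator epoch generator with known ground-truth coupling
    for end-to-end validation, plus zero-phase Butterworth filtering,
    artifact rejection, ERP subtraction for induced-activity isolation,
    and Hamming-tapered FFT band power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
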