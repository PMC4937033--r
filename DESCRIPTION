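Package: predeeg
Title: Analysis of EEG Markers of Predictive Processing Under Certain and
    Uncertain Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for task EEG studies of prediction under
    certainty and uncertainty: stimulus-stream generation and labelling for a
    visual target-detection paradigm with an embedded 100% predictive
    sequence, trial exclusion and pair-wise trial-count equalization,
    preprocessing (earlobe re-referencing, zero-phase band-pass filtering,
    spherical-spline bad-channel interpolation, epoching, amplitude-based
    artifact flagging), event-related potential measures (CNV window means,
    peak latency and amplitude, windowed scans), Morlet wavelet
    time-frequency power and the phase-locking factor with a Rayleigh
    criterion, a bespoke inference layer (split-plot 2x2 mixed ANOVA,
    exhaustive paired permutation tests, randomization tests, mass-univariate
    electrode-by-window scans with an adjacency rule, Spearman correlation),
    behavioral scoring with a reaction-time prediction index, and a
    multi-subject synthetic task-EEG generator that emulates the assumed data
    structure so that every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
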