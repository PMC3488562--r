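Package: phaselagr
Title: Weighted Phase Lag Index and Stability Analysis for Artifact-Resistant EEG Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting event-locked cognitive dynamics in
    multichannel EEG through phase-lag functional connectivity. Implements the
    weighted phase lag index (WPLI) over sliding windows, a WPLI stability
    statistic (the coefficient of variation of WPLI over a trailing window),
    event-locked epoching and deflection statistics, principal-component
    topography of pairwise responses, and channel quality control
    (variance, kurtosis, and neighbour-correlation rules) with average
    re-referencing. Includes a synthetic multichannel EEG generator with
    known phase-lagged coupling, zero-lag common sources, gait-locked
    artifacts, and oddball event schedules, so every stage of the pipeline
    can be validated against ground truth, plus a streaming (on-line) mode
    using causal filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
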