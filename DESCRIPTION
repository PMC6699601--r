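Package: teamneuro
Title: Team Neurodynamics from Multichannel EEG Power Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic-dynamics modeling of team EEG hyperscanning data.
    Per-second band power is discretized into low/average/high levels,
    assembled into team neurodynamic symbols over a 3^n state space, and
    summarized by sliding-window Shannon entropy expressed as neurodynamic
    information (NI) in bits. Includes a synthetic-data generator with known
    organization epochs and cross-member coupling, member-level NI
    decomposition, shuffle-baseline envelopes, lagged cross-correlation,
    frequency-band and scalp-region aggregation, event bracketing, raw-level
    composition analyses, and nonparametric contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
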