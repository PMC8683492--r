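Package: lettercue
Title: Spatial Cueing Analysis for Multi-Letter Partial-Report Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing partial-report
    letter-recognition experiments with exogenous and endogenous spatial
    pre-cues. Builds balanced factorial trial lists (cue validity by
    cue-target onset asynchrony by letter position), simulates trial-level
    responses from a parametric observer with W-shaped positional
    sensitivity and a transposition/misidentification error mixture, and
    computes M-alternative forced-choice sensitivity (d'), cue
    benefit/cost/total-effect statistics, serial-position and crowding
    summaries, probit-linearised error differences, and split-half
    reliability with Spearman-Brown correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
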