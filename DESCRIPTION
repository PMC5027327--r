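Package: neurotree
Title: Decision-Tree Pattern Discovery in Multi-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for discovering interpretable patterns
    in multi-channel EEG recordings with decision trees. Simulates seeded
    32-channel 10-20 montage sessions with band-limited,
    lobe-specific discriminative activity; preprocesses raw signals with a
    Butterworth band-pass, squaring, and buffered averaging into labeled
    feature tables; balances, min-max normalizes and peak-groups those
    tables; induces C4.5-style decision trees (gain-ratio splits on numeric
    attributes, minimum leaf size as a fraction of the data, pessimistic
    pruning); extracts root-to-leaf rules; and attributes tree splits to
    brain lobes via the electrode montage, supporting group comparisons of
    which cortical regions a tree deems informative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
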