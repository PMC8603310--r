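Package: accentobs
Title: Ideal-Observer Analysis of Adaptation to Non-Native-Accented Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether exposure-driven adaptation to a
    non-native accent is expected from the statistics of the speech a
    listener hears. Phonetic categories (syllable-final /d/ vs. /t/) are
    modeled as multivariate Gaussian distributions over three duration cues
    (preceding vowel, closure, burst release); cue values are first
    corrected for segmental, supra-segmental and talker context by per-cue
    linear regression (C-CuRE-style normalization). Condition-specific
    Bayesian ideal observers predict category-goodness ratings for test
    tokens, which are compared against listeners' z-scored Likert ratings
    via item-level agreement and trial-level (mixed-effects) regression.
    Includes a hierarchical bootstrap that down-samples one experiment to
    the size and structure of another to separate power from true effect
    differences, and a synthetic-data generator so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    tibble,
    dplyr,
    readr,
    rlang,
    lme4,
    lmerTest,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
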