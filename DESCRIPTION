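Package: cessbounds
Title: Outcome Conventions and Attrition Bounds for Automated Smoking
    Cessation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting abstinence outcomes of fully automated
    Internet-based smoking cessation trials with severe follow-up attrition.
    Implements the three standard outcome conventions (observed,
    missing = smoking, missing = quit), worst-case and reference-trial
    anchored bounds on the true quit rate, condition-comparison statistics,
    cost-per-quitter arithmetic, and a synthetic cohort generator with a
    missing-not-at-random follow-up response mechanism so that every
    analysis stage can be verified in simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
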