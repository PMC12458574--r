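Package: ruleshift
Title: Rule-Shifting Task Simulation and Bayes-Optimal Confidence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying metacognitive bias and evidence tracking in
    intra-/extra-dimensional (ID/ED) rule-shifting tasks with trial-by-trial
    confidence ratings. Provides a deterministic task engine (covert rule
    shifts every 6-11 trials over three difficulty levels), a Bayes-optimal
    observer that converts feedback into posterior beliefs over stimulus
    features and derives General Certainty (scaled inverse posterior entropy)
    and Choice Certainty (posterior mass on the chosen stimulus), a synthetic
    two-group cohort generator emulating an OCD-versus-control confidence
    structure (stable negative confidence intercept with stronger coupling to
    choice certainty), and a mixed-effects analysis pipeline: exclusion and
    reaction-time filters, shift-aligned summaries, BIC-based functional-form
    selection, post-shift recovery models, feedback-sensitivity models,
    normative confidence regressions with collinearity diagnostics, and a
    parameter-recovery driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    car,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
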