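Package: lstema
Title: Latent State-Trait Reliability of Ambulatory Cognitive Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how reliably smartphone-administered
    cognitive control tasks (color Stroop, go/no-go) measure within-person
    fluctuation in ecological momentary assessment (EMA) designs. Implements
    trial-level scoring with validity restrictions, careless-responding
    screening, a first-order autoregressive latent state-trait model
    estimated by maximum marginal likelihood with variance-decomposition
    indices (overall reliability, common consistency, occasion specificity,
    within-subject reliability), generalizability-theory reliability of
    change with test-length and per-day curves, within/between correlation
    decomposition for convergent validity, multilevel context models with
    within-subject variance explained, and a synthetic-data generator that
    emulates the assumed latent structure at both the block-score and raw
    trial level.
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
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mvtnorm,
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
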