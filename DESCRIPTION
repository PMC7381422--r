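Package: condseq
Title: Temporal Condition-Pattern Mining in Matched Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering temporal condition patterns surrounding a
    clinical index event (such as incident pediatric obesity) in longitudinal
    electronic health record data. Provides a synthetic longitudinal EHR
    generator with configurable planted effects, index-visit cohort
    phenotyping with pre-/index-/post-index timing classes, greedy caliper
    matching of never-unhealthy-BMI controls, a vertical id-list SPADE
    frequent-sequence miner, and matched-pair McNemar tests with
    discordant-pair odds ratios, plus an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
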