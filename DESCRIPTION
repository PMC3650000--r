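Package: detpat
Title: Longitudinal Detection-Pattern Analysis with Mixed Directional FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating longitudinal binary detection histories (for
    example presence/absence of gut microbial taxa across early-life sampling
    days) to a continuous growth outcome such as the change in weight-for-age
    Z-score. Implements a time-specific analysis (per-taxon, per-day regression
    of the outcome on detection with mixed directional false discovery rate
    control across taxa and days) and a detection-pattern analysis (equivalence
    testing of pattern-group means to zero within a margin, mixed directional
    FDR control across taxa and testable patterns, a sequential right-side
    pattern reduction cascade at geometrically halved levels, and post-hoc
    crude-contrast screening). Ships a synthetic-cohort generator with Markov
    detection persistence and a Monte-Carlo harness that measures empirical
    error control, power, and pattern recovery.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
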