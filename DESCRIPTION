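Package: cmrextract
Title: Label-Efficient Extraction of Quantitative Measurements from
    Cardiac MRI Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for extracting quantitative cardiac magnetic
    resonance (CMR) measurements from free-text diagnostic reports with a
    small annotation budget. Provides a 21-measurement schema with aliases
    and physiologic reference ranges, standoff annotation input/output and
    interannotator agreement, alternative numerical token representations
    with exact offset maps, subword tokenization and 128-token windowing,
    a compact transformer token classifier trained with cross-entropy,
    span consolidation with digit merging and physiologic filtering,
    token-level macro-F1 evaluation with bootstrap confidence intervals
    and per-measurement ROC curves, learning-curve experiments, a seeded
    synthetic report generator for end-to-end testing, and person-time
    incidence-rate statistics (exact Poisson confidence intervals,
    two-sample rate comparisons, quartile and threshold stratification)
    for validating extractions against clinical outcomes.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
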