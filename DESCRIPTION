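Package: cogsieve
Title: Validation Analysis for a Two-Step Cognitive Screening Sieve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate a brief digital cognitive-screening battery
    against reference neuropsychological testing. Implements the battery's
    score definitions (five-word recall, number coding, trail making, system
    usability scale, norm-based standardization), a seeded synthetic cohort
    generator calibrated to published case-control distributions, digital
    versus reference concordance with Benjamini-Hochberg correction, a
    two-step clinician-guided "sieve" classifier with constrained threshold
    optimization (maximize specificity under a sensitivity floor), a
    ridge-penalized logistic classifier, a stratified fivefold
    cross-validation harness, and covariate-adjusted group comparisons.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
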