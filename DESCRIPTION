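Package: ruraldce
Title: Discrete Choice Experiment Analysis of Rural Job Preferences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing paired discrete
    choice experiments (DCEs) on health-workforce job preferences. Builds
    blocked orthogonal main-effects paired-choice designs with diagnostics
    (level balance, orthogonality, overlap, utility balance), simulates
    respondents under conditional-logit, mixed-logit and latent-class
    data-generating processes, estimates conditional logit, panel mixed
    logit (simulated maximum likelihood with Halton draws) and latent-class
    logit (EM with AIC class selection) models, and computes the standard
    post-estimation statistics: willingness-to-accept with delta-method or
    Krinsky-Robb intervals, class-share-weighted relative importance of
    attributes, and marginal uptake-rate changes for attribute-level policy
    moves. Ships the attribute schema and published preference estimates of
    a rural-job DCE among Ethiopian graduating medical students as
    reproducible reference conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
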