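Package: msbr
Title: Probabilistic Benefit-Risk Assessment of Methylprednisolone in
    Multiple Sclerosis Relapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantitative probabilistic benefit-risk
    assessment of high-dose and low-dose methylprednisolone against no
    treatment in multiple sclerosis relapses. Effectiveness and non-serious
    adverse-event risks are estimated by hierarchical beta-binomial
    meta-analysis with Metropolis-Hastings sampling; serious adverse-effect
    risks are bounded by reporting ratios derived from spontaneous case
    reports and sampled from plausible interval distributions; utilities are
    sampled uniformly from order-constrained polytopes encoding qualitative
    clinical preferences; and treatment alternatives are compared by
    expected utility and preference rates over Monte-Carlo iterations,
    including a full sensitivity grid and median-fixation uncertainty
    attribution. Study-arm tables, serious-effect definitions and upper risk
    limits are shipped as plain-text fixtures, and a synthetic-data module
    generates study arms and case-report collections with known truth for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
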