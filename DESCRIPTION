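Package: pcrbayes
Title: Bayesian Beta-Binomial Comparison of Pathologic Complete Response
    Between Two Patient Strata
Version: 0.1.0
Authors@R:
    person("pcrbayes", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Conjugate beta-binomial A/B comparison of a binary clinical
    endpoint (pathologic complete response after neoadjuvant chemotherapy)
    between two patient strata, such as carriers and non-carriers of a
    BRCA1 founder mutation in triple-negative breast cancer.  Provides
    prior elicitation, posterior updating, equal-tailed credible
    intervals, Monte Carlo probability of superiority with exact
    quadrature oracles, the relative-improvement (lift) ratio
    distribution with percentiles and threshold exceedance
    probabilities, frequentist 2x2 odds ratios with profile-likelihood
    confidence intervals, descriptive group-comparison tests
    (pooled/Welch t, F, chi-square), a synthetic two-stratum cohort
    generator with parameter-recovery studies, and a command-line
    interface producing JSON and markdown reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
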