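Package: primecause
Title: Causal Priming Effects in Between-Subjects Word-Fragment-Completion
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines, estimates, and tests causal repetition-priming effects
    in between-subjects word-fragment-completion experiments under the
    potential-outcomes framework. Provides the difference-in-proportions
    priming estimator (pooled and word-averaged), the pooled two-proportion
    z test and unpooled Wald confidence interval, the multinomial
    processing tree decomposition of the priming effect, covariate
    adjustment by logistic regression, propensity-score matching for
    non-randomizable exposures, and an inclusion/exclusion
    (process-dissociation) contrast. A potential-outcomes simulator
    realises both counterfactual outcomes for every subject-word pair, so
    the unobservable average priming effect is computable and every
    estimator can be checked by exact identity or parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
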