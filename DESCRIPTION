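Package: embedaudit
Title: Auditing Out-of-Distribution Generalization of Embedding-Based Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to fit regularized regressions of behavioral targets on
    prompt-derived embedding features and to audit how such models generalize.
    Implements random out-of-sample, target-quantile out-of-distribution and
    condition hold-out evaluation regimes, the SD score (a train/test exchange
    diagnostic of extrapolation failure), log-SD consistency summaries, and
    ordinal-adequacy tests that compare predicted against observed orderings of
    condition or cluster means. Ships seeded synthetic generators for templated
    number prompts, condition studies, autocorrelated trial series and
    horizon-task choices, plus a synthetic encoder that reproduces the local
    similarity structure of language-model embeddings, so the full audit
    pipeline runs without any external model or download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
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
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
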