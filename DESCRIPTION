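Package: lstmm
Title: Multimethod Latent State-Trait Models for Random and Fixed Situations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, estimates, and evaluates multimethod latent state-trait
    models for random and fixed situations (MM-LST-RF) and their reduced forms
    (LST-RF, MM-LST). Constructs the structured confirmatory factor model from
    a factorial measurement design (indicators x methods x occasions x fixed
    situations), applies equivalence and measurement-invariance constraints,
    estimates parameters by normal-theory maximum likelihood with listwise or
    full-information treatment of missing data, and reports fit indices,
    variance-decomposition coefficients (consistency, occasion specificity,
    reliability), cross-situation commonality and situation specificity,
    latent change-score interaction effects, and sequential measurement
    invariance tests with Chen's decision criteria. Includes a model-based
    simulator for parameter-recovery studies and export of models in a
    standard SEM model-description dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
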