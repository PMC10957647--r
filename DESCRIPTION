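Package: smchd
Title: Survivor Selection and the Causal Hazard Difference in Additive
    Hazard Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how the observed hazard difference from a
    randomized trial deviates from the causal hazard difference when the
    additive treatment effect on the hazard is heterogeneous across
    individuals. Provides closed-form estimands (causal hazard difference,
    survivor-marginalized causal hazard difference and their integrated
    curves) via Laplace transforms of the effect-modifier law, a structural
    causal survival simulator with Gaussian-copula dependence between
    frailty and effect modifier, Monte-Carlo survivor-conditional
    expectations for the dependent case, and a from-scratch least-squares
    estimator of Aalen's additive hazard model with pointwise confidence
    bands, so that a time-invariant but heterogeneous effect can be seen to
    produce a non-linear cumulative regression curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
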