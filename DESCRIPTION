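Package: bayespta
Title: Bayesian Pure-Tone Audiometry with Gaussian Process Mixture Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive pure-tone audiometry driven by a learnable mixture of
    Gaussian process priors over hearing thresholds. Provides the probit
    response model on the Bark frequency scale, maximum-likelihood model
    learning from annotated audiogram data sets (EM for a full-covariance
    Gaussian mixture, Kullback-Leibler matching of GP components, and a
    side-information lookup table for the mixing weights), Laplace posterior
    inference with evidence-weighted mixture posteriors, closed-form optimal
    stimulus selection by Bayesian active learning by disagreement (BALD),
    a synthetic audiogram population generator, and a simulation harness for
    benchmarking threshold-estimation error against trial count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
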