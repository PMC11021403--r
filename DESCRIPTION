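Package: tdisc
Title: Hierarchical Bayesian Temporal Discounting and Transdiagnostic
    Symptom Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying individual differences in temporal
    discounting and their association with transdiagnostic psychiatric
    symptom dimensions. Provides hierarchical Bayesian estimation of
    condition-specific log discount rates (hyperbolic, exponential and
    quasi-hyperbolic families) from binary intertemporal choices,
    PSIS-LOO and WAIC predictive-accuracy machinery, Bayesian (BEST) and
    frequentist inference for time-framing and reward-magnitude effects,
    heterogeneous (Pearson/polyserial/polychoric) correlation matrices
    with maximum-likelihood exploratory factor analysis and oblimin
    rotation, robust-SE regression layers with Holm correction, an exact
    power computation for correlation designs, and a synthetic-cohort
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    sandwich,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    e1071,
    withr
Config/testthat/edition: 3
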