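Package: panelcause
Title: Causal Forecasting and Prediction in Linear Cross-Lagged Panel Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for distinguishing forecasts of the effects of do-type
    interventions from predictions of future outcomes in linear Gaussian
    structural causal models for cross-lagged panel designs. Computes
    implied joint moments of the model (with or without random-intercept
    unobserved heterogeneity), performs graph surgery for the do-operator,
    derives interventional, conditional and person-specific interventional
    distributions, evaluates treatment-success probabilities over an
    acceptable outcome range, finds optimal interventional levels, and
    ships a seeded panel simulator plus maximum-likelihood estimation of
    the model parameters from panel data. Includes graph-theoretic
    identification utilities (d-separation, backdoor paths, minimal
    adjustment sets) on DAGs with bidirected edges.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
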