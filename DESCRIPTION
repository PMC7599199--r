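Package: polikst
Title: Polytomous Knowledge Structures and the Polytomous Local
    Independence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for knowledge space theory with polytomous (ordered
    multi-level) items. Implements the polytomous local independence
    model (PoLIM), a latent-class model in which each respondent occupies
    a latent state assigning a response level to every item and observed
    responses deviate from the state through per-item row-stochastic
    error matrices. Provides level metrics and monotonicity diagnostics
    (modality, delta-monotonicity and half-monotonicity, overall error,
    order-respecting metrics), a constrained reparameterization of the
    error matrices through overrate and underrate decay rates,
    maximum-likelihood estimation by EM with and without monotonicity
    constraints, closed-form minimum-discrepancy estimation under Hamming
    or Manhattan pattern-state distances, data-driven structure
    extraction by k-median clustering with minimax validation, and a
    parameter-recovery simulation study with bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
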