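Package: affectgen
Title: Affect-Congruent Attention in Compound Generalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how induced affect biases feature-based
    attention during compound generalization. Generates the three-phase
    probabilistic reward task (cue learning, simple-cue test, compound
    generalization with probe trials and an optional pre-induction baseline
    block), simulates cohorts from an attention-weighted valuation model with
    softmax choice and power-law decay of affect effects, fits the model
    family by hierarchical Bayesian MCMC with non-centered parameterization,
    compares variants by WAIC, runs model- and parameter-recovery studies,
    and computes model-free behavioral summaries, participant exclusion
    filters, and eye-tracking area-of-interest relative looking time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
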