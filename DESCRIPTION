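Package: compmaxent
Title: Compositional Maximum Entropy Models for Relative-Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits maximum-entropy exponential-family models to compositional
    data on the probability simplex (the CME model) using a simplex-adapted
    pseudolikelihood with stable closed-form conditional partition integrals.
    Includes a Metropolis Monte-Carlo sampler on the simplex for simulating
    from fitted models, a deterministic quadrature oracle for small systems,
    a competitive Lotka-Volterra simulator for generating synthetic
    relative-abundance datasets, and a logit-normal (logistic-normal)
    precision-matrix baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
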