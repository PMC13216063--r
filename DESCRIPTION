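Package: catsnet
Title: Concept-Abstraction Gated Networks and Representational Similarity Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a dual-module neural architecture in which a
    task-solving perceptron is hierarchically gated, layer by layer, by
    multiplicative signals derived from a low-dimensional concept vector.
    Provides the alternating two-phase training procedure (network learning
    and concept learning with uniform noise injection), functional-entropy
    and basis-vector specificity probes of the learned concept space,
    gating-weighted gradient class-activation maps, a leave-one-out
    teacher-to-student concept-communication protocol with repelling-loss
    concept expansion and a translation network, and a representational
    similarity analysis stack (partial Spearman RDM correlation, Mantel
    permutation test, Fisher-z aggregation, split-half reliability and
    z-domain noise-ceiling estimation). Includes synthetic-data generators
    for hierarchically structured feature clusters and subject/model RDM
    ensembles with known signal and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
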