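Package: driverSigDR
Title: Driver-Signal-Informed Prediction of Cancer Cell Drug Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the drug sensitivity (LN IC50) of cancer cell lines by
    characterizing cancer driver signals on a protein-protein interaction
    network. Driver-gene seeds are propagated by random walk with restart,
    the propagation ranking is scored against pathway gene sets by preranked
    GSEA to select a pathway signature, and per-cell pathway activities are
    computed by single-sample GSEA. Binary driver mutation profiles and
    1024-bit circular (Morgan) drug fingerprints are embedded by
    autoencoders, and a feedforward network regresses LN IC50 from the
    concatenated pathway activities and embeddings under a unified
    prediction-plus-reconstruction loss. Includes split strategies for
    unseen-cell and unseen-drug generalization tests, Monte Carlo
    cross-validation, integrated-gradients attribution, pathway annotation
    of embedding dimensions, and a seeded synthetic-cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
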