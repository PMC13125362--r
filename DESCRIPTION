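Package: spiralnet
Title: Gated Multiscale Attention Depthwise-Separable Networks for
    Parkinsonian Drawing Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image-based screening of Parkinson's disease from
    structured drawing tasks (Archimedean spiral, meander, wave). Provides a
    seeded simulator of Parkinsonian drawing distortions (tremor, jitter,
    micrographia), a preprocessing pipeline that standardizes drawings into
    fused 256x256x3 inputs, a compact depthwise-separable convolutional
    network with a three-branch gated multi-head attention fusion module,
    a subject-independent training protocol with on-the-fly augmentation,
    a hybrid Bayesian-optimization/genetic-algorithm hyperparameter search
    driven by a sensitivity-weighted clinical score, deployment-oriented
    evaluation (ROC/PR, bootstrap subsets, rule-out/gray/rule-in triage,
    PPV/NPV), and superpixel Shapley-value attribution maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
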