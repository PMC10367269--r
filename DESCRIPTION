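Package: comorbnet
Title: Comorbidity Networks and Multiplex Disease-Gene Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted disease comorbidity networks from binary
    patient-by-diagnosis data (Fisher exact edge selection, phi correlation
    weights), detects disease clusters, derives subtype-discriminative
    comorbidity profiles with regularized logistic regression and forward
    selection, quantifies covariate-associated variance by multiple
    correspondence analysis, embeds the disease network in a
    multiplex-heterogeneous disease-gene network, propagates comorbidity
    profile seeds by random walk with restart, evaluates disease-gene
    recovery by leave-one-out link prediction against rewired and
    random-seed nulls, and prioritizes subtype-specific candidate genes.
    Includes a synthetic-data generator emulating cohorts with planted
    disease clusters, subtype markers, modular disease-gene maps,
    scale-free gene layers and ranked transcriptomic signatures.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    glmnet,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
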