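Package: funsig
Title: Functional Gene-Signature Embeddings for Compound-Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns functional embeddings of genes from weighted hypergraphs
    built on ontology annotations and expression-derived gene sets, using
    random walk with restart to define graph proximity and a contrastive
    negative-sampling objective to place functionally similar genes close
    together. Gene signatures are aggregated into consensus vectors with
    per-gene weights that down-weight outlier genes. A Siamese neural
    classifier scores whether a compound signature and a genetic-perturbation
    signature share a target; per-context predictions are combined by
    consensus rank aggregation and fused with activity-profile evidence via
    imbalance-corrected logistic regression with non-negative weights.
    Includes a simulation benchmark for signature-similarity sensitivity and
    synthetic fixture generators so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
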