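Package: rhetclass
Title: Rhetorical Sentence Classification of Medical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level classification of medical abstracts into rhetorical
    sections (objective, methods, results, conclusion) by two routes: SCAN-loss
    clustering of sentence embeddings with nearest-neighbour consistency and an
    entropy regulariser against cluster collapse, and a supervised
    multi-encoder-cascade classifier that augments each embedding through a
    constant-shift perturbation, an autoencoder and a denoising autoencoder,
    cross-supervised by dynamic-convolution layers. Includes a seeded synthetic
    corpus and embedding generator (Chinese or English template abstracts),
    a deterministic hashing sentence encoder with a label-supervised adapter,
    Hungarian cluster-to-label evaluation, and a reproducible pipeline with
    run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
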