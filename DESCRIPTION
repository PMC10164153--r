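Package: mdassoc
Title: Microbe-Drug Association Prediction from Bipartite Interaction Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate microbe-drug associations from a sparse
    binary bipartite adjacency matrix. Interaction-profile similarities
    (Gaussian interaction-profile kernel and cosine) feed a restart random
    walk that yields per-node diffusion profiles, while a stacked
    autoencoder whose output layer is enhanced by multi-head self-attention
    learns node attribute features from similarity matrices. Diffusion
    profiles, adjacency copies and attribute features are concatenated into
    integrated feature matrices and all drug-microbe pairs are scored by a
    sigmoid inner product. Includes a k-fold cross-validation harness with
    leakage-safe per-fold similarity recomputation, an attention ablation,
    hyperparameter sweeps, and a seeded synthetic bipartite generator with
    planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
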