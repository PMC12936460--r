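Package: fedcxr
Title: Cross-Silo Federated Averaging Simulator for Chest X-Ray Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single-process simulator of cross-silo federated learning for
    binary chest X-ray image classification. Pools a labelled image
    directory (or a built-in synthetic generator of two-class X-ray-like
    images), partitions the training data into equal IID client shards,
    trains a three-layer multilayer perceptron at each client with
    SGD-with-momentum and learning-rate decay, aggregates client parameters
    by data-proportional federated averaging (FedAvg), evaluates the global
    model on a central held-out test set every communication round, and
    selects the optimal global model by minimum global loss. All gradients
    are exact analytic backpropagation; every stage is deterministic under
    a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
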