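Package: fedchain
Title: Blockchain-Coordinated Federated Learning with Adaptive
    Differential Privacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale simulator and library for federated learning on
    distributed clinical data coordinated by a permissioned blockchain.
    Devices train local models on tabular clinical records and release
    per-round parameter updates under adaptive differential privacy
    (exponential-moving-average clipping threshold, L2 clipping, Gaussian
    noise); a reputation-weighted verification committee selected by
    consistent hashing screens the updates with multi-KRUM, endorses the
    qualified ones by majority signature, and commits them to a SHA-256
    hash-chained block ledger.  Cumulative privacy loss is tracked with a
    moments accountant (log-moments of the subsampled Gaussian mechanism,
    additive composition, tail-bound conversion to an (epsilon, delta)
    guarantee).  A poisoning harness applies label-flipping attacks to a
    configurable fraction of devices and reports attack success rates and
    detection precision/recall.  A seeded generator for Pima-like diabetes
    data makes every component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
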