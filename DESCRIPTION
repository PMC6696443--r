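Package: cgardp
Title: Drug-Disease Association Prediction from Heterogeneous Networks with
    Convolutional and Gated Recurrent Path Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-disease associations on a two-layer heterogeneous
    network built from a drug-drug similarity matrix, a disease-disease
    similarity matrix and a binary association matrix. For each drug-disease
    pair a convolutional encoder learns a local representation from the pair's
    stacked similarity/association feature matrix, while a bidirectional gated
    recurrent unit with path-level attention encodes enumerated drug-to-disease
    paths; the two softmax heads are combined into a convex association score.
    Includes per-drug five-fold cross-validation with ranking metrics (ROC and
    precision-recall areas, top-k recall, paired Wilcoxon comparisons), a
    planted block-model generator of synthetic heterogeneous networks, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse,
    rlang,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
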