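Package: pepstack
Title: Descriptor-Based Prediction and Proteome Mining of Cell-Penetrating
    Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting cell-penetrating peptides from sequence.
    Computes CTD (composition/transition/distribution) physicochemical
    descriptors over seven three-class property partitions, the Guruprasad
    instability index and a suite of global descriptors; reduces the
    descriptor space by correlation pruning and L1-regularized
    cross-validated selection; classifies with a stacked ensemble of
    k-nearest neighbors, gradient-boosted trees and a random forest; and
    mines candidate peptides from proteomes digested in silico with a
    35-rule enzymatic cleavage registry. Includes a synthetic-data
    generator emulating cationic/amphipathic peptides against a background
    composition so the full pipeline is reproducible without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
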