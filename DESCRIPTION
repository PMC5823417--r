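Package: ehcforest
Title: Cluster-Augmented Random Decision Forests for Hepatobiliary
    Disorder Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an intelligence-integrated diagnostic pipeline for
    four-class hepatobiliary disorder data (alcoholic liver damage, primary
    hepatoma, liver cirrhosis, cholelithiasis): agglomerative hierarchical
    clustering with a variance-weighted distance function, whose cluster
    assignments augment the feature set of a forest-RI random decision
    forest.  Provides five model variants (RF, ERF, HC-RF, HC-ERF,
    EHC-ERF), a synthetic clinical tabular data generator with controllable
    class separability and latent cluster structure, out-of-bag error
    estimation, and a seven-metric evaluation report (accuracy, true
    positive rate, precision, F-measure, Cohen's kappa, probabilistic MAE
    and RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
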