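Package: hnncarc
Title: Hybrid Neural Network Models for Chemical Carcinogenicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts chemical carcinogenicity from SMILES strings and
    molecular descriptors with a hybrid neural network that merges a
    character-level convolutional branch over embedded SMILES with a
    feed-forward branch over numeric descriptors. Provides binary and
    ternary carcinogenicity classification and quantitative pTD50
    regression, the fixed 94-character ASCII SMILES index codec and the
    legacy training-set one-hot encoder, label harmonization across
    carcinogen source agencies (MEG, NTP, IARC, JSOH, NIOSH, CPDB, CCRIS,
    DrugBank), descriptor completeness filtering, ensemble baseline
    learners with a seven-way consensus regressor, micro-averaged
    multiclass evaluation metrics, a repeated random-split evaluation
    protocol, and a synthetic structure-activity data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    xgboost,
    rpart,
    kernlab,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
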