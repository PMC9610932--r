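Package: bcfqsar
Title: QSAR Models for the Fish Bioconcentration Factor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Development, validation and application of quantitative
    structure-activity relationship (QSAR) models for the fish
    bioconcentration factor (log BCF). Provides a hydrogen-aware SMILES
    engine, the nine topological and electrotopological-state descriptors
    used by the published six-descriptor multiple linear regression model
    and the four-descriptor linear discriminant model, the frozen published
    regression equation with its Williams-plot applicability domain, the
    complete model-building machinery (descriptor pre-reduction, step-up
    variable subset selection, genetic-algorithm selection for LDA,
    k-fold cross-validation, Y-scrambling), regulatory B/not-B
    classification with accuracy/precision/sensitivity/specificity and
    ROC/AUC metrics, a resilient-backpropagation multilayer perceptron,
    and seeded synthetic-data generators that emulate the modelled data
    structure for testing and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
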