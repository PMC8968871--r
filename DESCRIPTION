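Package: isomerMS
Title: Chemometric Differentiation of Positional Isomers from
    Multi-Voltage Ambient Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for differentiating positional ring isomers of
    small molecules (e.g. novel psychoactive substances) from
    multi-voltage in-source collision-induced dissociation mass
    spectra acquired on ambient ionisation time-of-flight
    instruments. Provides a synthetic spectrum generator that
    emulates a weekly QuickStrip-card study design with batch
    drift, fixed-width m/z binning of centroided spectra into a
    sample-by-variable abundance table, percent-abundance variable
    selection with per-voltage refinement, ion-current and
    vector-length normalisation, multiway ANOVA screening, and
    three classifier families with conclusive/inconclusive decision
    rules: a per-bin Welch-test counting classifier with
    replicate-averaged ROC curves, linear discriminant analysis
    with equal priors and posterior thresholds, and a random forest
    with out-of-bag vote proportions, permutation importance,
    recursive variable halving, triplicate decision rules and
    external-batch application. Includes leave-one-card-out, 80/20
    and same-day validation harnesses and success/inconclusive/error
    rate tables over a threshold sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'anova-descriptives.R'
    'benchmark.R'
    'binning.R'
    'evaluation.R'
    'feature-selection.R'
    'forest.R'
    'isomerMS-package.R'
    'lda.R'
    'pipeline.R'
    'synthetic-data.R'
    'utils.R'
    'welch.R'
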