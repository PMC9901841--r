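Package: permstack
Title: Stacked Neural-Network QSAR Models for PAMPA Membrane Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the effective membrane permeability (logPe)
    of small molecules measured by the parallel artificial membrane
    permeability assay (PAMPA). Converts raw PAMPA plate measurements to
    logPe, computes molecular descriptors from SMILES or SDF input, selects
    descriptors by recursive feature elimination with random forests under
    repeated cross-validation, trains feedforward multilayer perceptrons with
    resilient backpropagation (Rprop+ with weight backtracking), stacks them
    into an ensemble with a neural meta-learner, and flags unreliable
    predictions with an ensemble-standard-deviation applicability domain.
    Includes a synthetic data generator with known ground truth, gain-curve
    relative Gini scoring, a six-descriptor linear baseline, and an
    interpretable surrogate regression tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
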