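Package: pertcycle
Title: Cycle-Consistent Prediction of Cellular Responses to Perturbations
Version: 0.1.0
Authors@R: person("Alex", "Moran", email = "alex.moran@example.org",
    role = c("aut", "cre"))
Description: Predicts bulk and single-cell transcriptional or proteomic
    responses to chemical and genetic perturbations. A dual
    encoder-decoder pair maps expression profiles into a shared latent
    space in which a perturbation acts as vector addition; a graph
    attention network encodes drug molecules (from SMILES) into that
    space, and a one-layer encoder handles genetic perturbations.
    Paired data are fit by reconstruction plus bidirectional mean
    squared error; unpaired single-cell data are fit with adversarial
    domain alignment and cycle-consistency constraints. Includes a
    synthetic-data generator with known ground truth, an evaluation
    suite (coefficient of determination, explained variance,
    differential-expression subsets), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
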