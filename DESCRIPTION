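Package: dtakit
Title: Drug-Target Binding Affinity Modelling with Message Passing and
    Self-Supervised Protein Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts real-valued drug-target binding affinity from a molecule
    SMILES string and a protein amino-acid sequence.  Molecules are encoded
    with an undirected cross-message-passing network over the atom/bond graph;
    proteins are encoded by combining a masked-language-model branch with a
    contrastive-predictive-coding branch (segment convolutions plus a gated
    recurrent autoregressor), the two embeddings being concatenated per
    segment.  A molecule-to-protein attention layer re-weights the protein
    embedding before a multilayer perceptron regresses the affinity.  Includes
    a reverse-mode automatic-differentiation core, seeded synthetic-data
    generators for molecules, proteins and affinity labels, dataset readers,
    deterministic splits, pretraining and training loops, checkpointing, and
    the mean-squared-error and concordance-index evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
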