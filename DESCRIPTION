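Package: ddgfuse
Title: Multiscale Feature Fusion for Predicting Protein Stability
    Changes from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of the change in protein folding
    free energy (ddG, kcal/mol) caused by a single-point mutation. A
    global change vector (the difference of mean-pooled residue-level
    protein-language-model embeddings of the mutant and wild-type
    sequences) and a 25-dimensional local mutation descriptor (relative
    solvent accessibility, dihedral-angle encodings, disorder,
    physicochemical property changes and secondary-structure
    probabilities) are each encoded to 128 dimensions, fused through
    learnable element-wise weights and decoded by a small convolutional
    regressor. Includes homology-aware cross-validation with fold
    ensembling, an antisymmetry-aware evaluation suite for matched
    direct/reverse mutation pairs, deterministic synthetic providers for
    embeddings and structural annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
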