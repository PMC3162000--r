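Package: coilmrf
Title: Coiled-Coil Detection and Oligomerization-State Prediction with
    Markov Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts coiled-coil regions in protein sequences and their
    oligomerization state (dimer versus trimer), residue by residue.  A
    chain-structured Markov random field over 127 hidden heptad states
    (non-coil, plus 63 dimer and 63 trimer states indexed by heptad a-g
    and location 1-9) is decoded exactly by the forward-backward
    algorithm.  Singleton potentials are built from eight sequence
    features: per-heptad residue log-probabilities, distance-1..7
    pairwise correlation statistics and Eisenberg-scale hydrophobicity at
    the a and d core positions, combined by a class-weighted multinomial
    logistic regression trained on register-annotated coiled-coil
    families and register-randomized negative windows.  Includes readers
    and writers for FASTA and 4-line annotated family records, a
    synthetic family generator, and a nested leave-family-out
    cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    optparse
Config/testthat/edition: 3
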