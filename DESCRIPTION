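Package: angiopept
Title: Prediction and Sequence Analysis of Anti-Angiogenic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating labelled peptide datasets, computing amino
    acid and dipeptide composition features, residue and positional
    propensities, discriminative gapped sequence motifs, and for training
    and cross-validating terminus-aware machine-learning classifiers of
    anti-angiogenic activity. Includes redundancy reduction by greedy
    identity clustering, length-matched negative sampling from a background
    proteome, a synthetic data generator emulating the compositional bias of
    anti-angiogenic peptides, model routing by peptide length, and
    single-mutant analog scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
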