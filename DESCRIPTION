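Package: oncorank
Title: Kernel One-Class SVM Prioritization of Cancer Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate cancer driver genes (oncogenes and tumor
    suppressor genes) by training a one-class support vector machine on
    precomputed gene kernels.  Gene similarity combines somatic-mutation
    feature vectors (damaging missense counts, loss-of-function counts,
    positional entropy) with a diffusion kernel over a protein-protein
    interaction network.  Supports a pan-cancer single-task mode and
    cancer-type-specific multitask modes in which driver information is
    shared across diseases through task-descriptor kernels.  Includes the
    consistency-error evaluation protocol (repeated k-fold cross-validation
    with inner regularization tuning), degree-binned network randomization
    controls, a fully seeded synthetic-data generator with planted drivers,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
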