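Package: retfid
Title: Cell-Identity Scoring and Fidelity Benchmarking of Retinal Organoid scRNA-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how faithfully retinal organoid single-cell RNA-seq
    datasets recapitulate the fetal and mature human retina. Computes rank-based
    differential-stability cell-identity scores per gene and cell type within
    each batch, builds batch-averaged mature, fetal and age-resolved reference
    atlases, discovers maturation-associated genes by correlating identity
    scores with developmental age, validates marker genes by kNN and
    random-forest classification, and scores organoid datasets against the
    references with six fidelity metrics (mature and fetal cell identity,
    maturation, cell-type coverage, cell-type proportion, and off-target cell
    fraction). A negative-binomial simulator with planted markers, batch
    effects, age ramps and off-target cells makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    mclust,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
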