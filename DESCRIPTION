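Package: metaboSL
Title: Synthetic-Lethal Interaction Prediction from Context-Specific
    Metabolic Models and Mutation Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts synthetic-lethal (SL) gene pairs in cancer cell lines
    by combining constraint-based metabolic modelling with somatic mutation
    data. Builds per-cell-line context-specific metabolic models from
    expression profiles with an iMAT-style extraction and a threshold grid
    search, simulates flux-balance-analysis gene knockouts to obtain a
    KO-score matrix, associates KO scores with driver-gene mutation status
    through a filtered, noised two-sample t-test screen with
    Benjamini-Hochberg correction, and validates predicted pairs against
    CRISPR, shRNA and drug-perturbation dependency matrices via
    hypergeometric enrichment. Includes preranked gene-set enrichment of SL
    partner lists, deterministic toy models and planted-SL synthetic data
    generators, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    fgsea,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'lp-solver.R'
    'gpr.R'
    'model.R'
    'fba.R'
    'context.R'
    'slscan.R'
    'enrichment.R'
    'fixtures.R'
    'io.R'
    'metaboSL-package.R'
    'validation.R'
    'pipeline.R'
    'utils.R'
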