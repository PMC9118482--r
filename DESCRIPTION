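Package: nucmeta
Title: Meta-Prediction and Consistency Analysis of Nucleic-Acid-Binding
    Residue Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residue-level analysis toolkit for protein DNA- and RNA-binding
    annotations. Fuses a disorder-trained and a structure-trained
    binding-propensity track into a meta-predictor (min/max/average consensus
    and a small windowed feed-forward neural network), evaluates predictors
    with threshold-standardized metrics (AUC, sensitivity at fixed false
    positive rate, specificity at fixed true positive rate) and
    resampling-based paired significance tests gated by Anderson-Darling
    normality, processes experimental annotations (8-to-3-state secondary
    structure collapse, relative solvent accessibility, PDB chain selection,
    disorder from unresolved residues), quantifies cross-characteristic
    relations (disorder, secondary structure, accessibility, binding), and
    generates seeded synthetic datasets with the statistical structure of
    curated human-proteome benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    nortest,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'evaluate.R'
    'combine.R'
    'ffnn.R'
    'meta.R'
    'methods.R'
    'nucmeta-package.R'
    'significance.R'
    'relations.R'
    'validate.R'
    'synth.R'
    'tracks_io.R'
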