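Package: PepMIL
Title: Multiple-Instance Learning for MHC Class II Peptide Binding Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts MHC class II peptide binding affinity with a
    multiple-instance learning model. Each peptide is a bag of candidate
    binding-core substrings (9-mers, optionally 11-mers that add the two
    flanking residues), bags are embedded into a meta-space of training
    instances through minimum BLOSUM62 key-position distances, and an
    epsilon support vector regressor maps the embedding to a log-transformed
    IC50. Includes the ablation family of method presets (fixed-length bags,
    flexible-length bags, first-position limitation, key-position distance
    schemes), a stratified 5-fold cross-validation harness with per-allele
    ROC AUC, an exact one-tailed binomial sign test for comparing methods,
    and a motif-planted synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, e1071, jsonlite
Suggests: testthat (>= 3.0.0), Biostrings, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'PepMIL-package.R'
    'substitutionMatrix.R'
    'peptides.R'
    'bags.R'
    'synthetic.R'
    'embedding.R'
    'model.R'
    'evaluation.R'
    'cli.R'
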