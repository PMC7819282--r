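Package: conjointFP
Title: Conjoint Molecular Fingerprints for QSAR/QSPR Regression Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds conjoint molecular fingerprints by concatenating MACCS
    substructure keys (166 bits) with extended-connectivity fingerprints
    (ECFP, radius 2, folded to 2048 bits) into a single binary representation,
    and benchmarks the scheme against each standalone fingerprint and a
    two-member consensus ensemble across five regressor families (random
    forest, support vector regression, gradient boosting, LSTM and
    feed-forward neural networks) on lipophilicity (logP) and binding-affinity
    (pKi) regression tasks. Includes readers for SMILES/CSV and SDF property
    tables, a protein-ligand pocket featurization path (4.5 Angstrom atom
    filter with water and metal-ion removal), random and Bemis-Murcko scaffold
    splitters, grid-search hyperparameter tuning with k-fold cross-validation,
    the evaluation metrics used in lipophilicity benchmarking (RMSE, Pearson
    correlation, Tetko deviation bins), PCA projection of fingerprint space,
    and a synthetic-data generator that plants block-structured signal so the
    whole pipeline is testable without external datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    parallel,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    e1071,
    randomForest,
    xgboost,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fingerprints.R'
    'splitters.R'
    'evaluate.R'
    'nn.R'
    'models.R'
    'benchmark.R'
    'chem_io.R'
    'synthetic.R'
    'tune.R'
    'cli.R'
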