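Package: mtqsar
Title: Multitask Attentive Graph Networks for Kinase Selectivity QSAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates multi-target IC50 tables into sparse pIC50 datasets,
    trains a shared-trunk graph attention regressor with one output head per
    kinase target and a masked mean-squared-error loss, evaluates models with
    per-task and global R2/MAE/RMSE and threshold AUC, validates them by
    Y-randomization, attributes predictions to atoms through readout attention
    or gradient saliency with rank-sum substructure tests, and gates
    predictions with a distance-to-model applicability domain on Morgan
    fingerprints. Chemistry perception (standardization, featurization,
    fingerprints, drug-likeness, SMARTS matching, depiction) is performed by
    RDKit through a bundled batch backend script.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    xgboost
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' (or set options(mtqsar.python=) / MTQSAR_PYTHON).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
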