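Package: orthotarget
Title: Orthologue-Aware Ligand-Based Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates ligand-based target-prediction models that
    merge orthologue bioactivity data into human target training sets.
    Curates ChEMBL-style activity and PubChem-style inactivity tables
    (pChEMBL thresholds, assay confidence, element and molecular-weight
    structure filters), maps orthologue actives onto human targets through
    HomoloGene-style homology groups, samples putative inactives by sphere
    exclusion on ECFP_4 Tanimoto similarity, trains Platt-calibrated random
    forest, Bernoulli naive Bayes and linear SVM classifiers on 2048-bit
    Morgan fingerprints, and evaluates them with five-fold time-series
    cross-validation (precision, recall, F1, PR-AUC, BEDROC). Includes the
    bidirectional conflict, affinity-concordance and chemical-space audits
    used to justify cross-species bioactivity transfer, and a synthetic
    fixture generator so the whole pipeline runs without database downloads.
    Structure handling (canonical SMILES, descriptors, ECFP_4) is delegated
    to the Open Babel toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (>= 3.0, the 'obabel' executable on PATH)
Config/testthat/edition: 3
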