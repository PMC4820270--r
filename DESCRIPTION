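Package: ionpred
Title: Hierarchical Sequence-Based Prediction of Ion Channels and Their Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein sequence is an ion channel, whether a
    channel is voltage- or ligand-gated, and which of four voltage-gated
    subtypes (potassium, calcium, sodium, anion) it belongs to. Each stage
    combines a radial-basis-function support vector machine trained on an
    878-dimensional representation of the sequence (amino acid and dipeptide
    composition, physicochemical property statistics, predicted secondary
    structure, intrinsic disorder and relative solvent accessibility segment
    descriptors, and PSSM evolutionary-profile scores) with annotation
    transfer from the best BLAST hit against the labelled training set.
    Includes the full correlation-based feature selection protocol
    (fold-averaged point-biserial ranking, Pearson redundancy removal,
    wrapper backward elimination, and a PCA alternative), SVM hyperparameter
    grid search, cross-validation and jackknife evaluation, and a synthetic
    data generator so the whole pipeline is testable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
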