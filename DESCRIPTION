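Package: physiomap
Title: Physio-Metabolic MRI Biomarker Mapping and Radiomic Classification of Glioma IDH Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven pipeline for preoperative glioma IDH genotype
    classification from physio-metabolic MRI. Implements quantitative BOLD
    (qBOLD) mapping of oxygen metabolism (OEF, CMRO2, capillary and
    mitochondrial oxygen tension), dynamic susceptibility contrast (DSC)
    perfusion processing with gamma-variate first-pass fitting and automatic
    arterial input function selection, vascular architecture mapping (vascular
    hysteresis loop, microvessel type indicator, microvessel density, vessel
    size index), IBSI-style radiomic feature extraction (107 features per map),
    ReliefF plus wrapper feature selection with SMOTE class balancing, and five
    classifiers (MLP, adaptive boosting, random forest, 1D-CNN, LSTM) with
    support-weighted evaluation metrics. A digital phantom cohort generator
    forward-simulates raw multi-echo and DSC series for two tumor classes under
    two acquisition protocols so the whole pipeline runs and is tested without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    nnet,
    rpart,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
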