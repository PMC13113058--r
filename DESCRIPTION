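Package: pvlnet
Title: Multi-Modal Deep Learning for Residual Paravalvular Leak Prediction
    After Bicuspid-Valve TAVI
Version: 0.1.0
Authors@R:
    person("pvlnet", "developers", email = "pvlnet@example.org",
           role = c("aut", "cre"))
Description: Predicts residual moderate-or-greater paravalvular leak (PVL)
    after transcatheter aortic valve implantation (TAVI) in bicuspid aortic
    valve patients from pre-procedural CT and clinical covariates. Implements
    a multi-modal network (3D ResNet-18 imaging encoder over co-registered
    CT / aortic-root-mask / calcification-mask channels, a clinical MLP, and
    scaled dot-product cross-attention fusion), two-stage training with
    calcification-volume proxy pretraining and stratified cross-validated
    fine-tuning, a conventional five-classifier tabular baseline, a synthetic
    aortic-root CT phantom generator with a known outcome-generating process,
    Grad-CAM interpretability, and a full statistical evaluation harness
    (AUC, DeLong test, calibration and Brier score, decision-curve analysis,
    descriptive-table tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
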