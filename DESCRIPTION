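Package: neoecho
Title: Multi-View Spatio-Temporal Grading of Neonatal Pulmonary
    Hypertension from Echocardiogram Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Video-based assessment of pulmonary hypertension (PH) severity
    in newborns from 2D echocardiograms. Provides grayscale echo-video
    containers with lossless archive I/O, a synthetic echo simulator with
    severity-dependent septal morphology and ground-truth ventricle masks,
    sector masking and preprocessing, a per-sequence augmentation suite,
    segmentation-area frame selection and clip extraction, compact 2D and 3D
    residual-network classifiers trained with inverse-class-frequency
    resampling, clip-to-view-to-subject majority-vote aggregation with a
    confidence statistic, Grad-CAM saliency extended to spatio-temporal
    volumes, repeated stratified patient-level evaluation, and the clinical
    sPAP/mPAP pressure-estimation formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
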