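Package: ngtmonitor
Title: Lifecycle Tools for Nasogastric Tube Position Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the full lifecycle of a chest-radiograph
    nasogastric tube (NGT) position classifier: synthetic cohort, image and
    embedding generation with plantable concept drift; DICOM-style cohort
    curation (quality-control filters, keyword retention, majority-vote
    consensus, patient-grouped stratified splitting); a small trainable
    convolutional network ensemble with global-average-pooling embeddings,
    Hyperband tuning and Grad-CAM saliency; parametric 2-D embedding
    reduction (triplet-network and linear backends); explained-variance (R2)
    attribution of embeddings to metadata tags; a classifier two-sample
    concept-drift monitor combining random-forest out-of-bag probabilities
    with the two-sample Kolmogorov-Smirnov test; and an evaluation suite
    (confusion matrices, exact Clopper-Pearson intervals, bootstrap ROC AUC,
    calibration curves, Cohen kappa reader-agreement analytics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    ranger,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
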