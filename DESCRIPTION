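Package: patchCellularity
Title: Tumour Cellularity Estimation from H&E Breast Histology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classical computer-vision pipeline estimating residual tumour
    cellularity (TC) on hematoxylin-and-eosin breast tissue patches after
    neo-adjuvant treatment. Separates stain colours by K-means clustering in
    HSV space, enhances and segments nuclei (contrast enhancement, Otsu
    binarisation, watershed splitting of touching nuclei), extracts a
    three-level morphological feature table (per-nucleus geometry and texture,
    windowed regional concentrations and HSV histograms, duct/cluster
    morphometrics, global concentrations), selects key parameters by
    correlation against cellularity cross-checked with the lasso, classifies
    nuclei as benign or malignant (SVM, KNN, AdaBoost), and scores TC as the
    area fraction covered by dilated malignant nuclei. Ships a synthetic
    phantom generator with pixel-exact ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    e1071,
    class,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
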