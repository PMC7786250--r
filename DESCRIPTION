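Package: ipnwu
Title: Image Patch-Based Net Water Uptake from Non-Enhanced Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies net water uptake (NWU) in ischemic stroke from
    non-enhanced admission head CT using mirrored 30x30 image patches
    (IP-NWU) or segmented lesion regions overlaid from follow-up imaging
    (SR-NWU). Builds voxel-wise NWU ratio maps, extracts 13 first-order
    histogram radiomics features, and trains leave-one-out cross-validated
    classifiers (support vector machine, logistic regression, random
    forest) to predict malignant cerebral edema, with paired-AUC (DeLong)
    comparison, Youden cutoffs, intraclass correlation and Bland-Altman
    agreement statistics. Includes a synthetic head-CT phantom and cohort
    generator with known ground-truth water uptake so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
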