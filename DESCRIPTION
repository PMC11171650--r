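Package: lesionfd
Title: Box-Counting Fractal Dimension Analysis and Classification of
    Dermatological Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Minkowski-Bouligand (box-counting) fractal
    dimension of binary lesion masks derived from dermatoscopic
    photographs, and uses the per-lesion fractal dimension as the single
    feature for downstream lesion classification: diagnosis-group
    mapping (benign/malignant, melanoma/non-melanoma,
    metastatic/non-metastatic), rank-based group comparisons, ROC
    threshold screening, a two-stage fractal-dimension decision rule,
    and unsupervised structure discovery via PCA and iterated K-means
    with inertia and silhouette quality metrics. Ships a synthetic-data
    module that renders fractal rasters of analytically known dimension
    (Sierpinski carpet and triangle, Koch curve, squares, disks, lines)
    and simulates diagnosis-labelled fractal-dimension cohorts, so the
    whole pipeline is testable without any external image archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
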