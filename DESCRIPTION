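Package: fireice
Title: Fire-Ice Feature Fusion for Machine-Vision Seed Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A machine-vision pipeline for authenticating spine-date seed
    (Ziziphi Spinosae Semen) against its common market counterfeits from
    single-seed photographs. Extracts nine chromaticity features (RGB,
    CIELAB, HSI channel means over an Otsu-segmented foreground) and
    twenty-two texture features (six gray-level co-occurrence matrix
    statistics and sixteen Law's texture energies), fuses each family into
    a scalar index (the "fire" value for color, the "ice" value for
    texture), and evaluates the fused two-dimensional representation with
    PCA, PLS-DA (NIPALS, VIP scores, permutation testing), per-feature
    ANOVA marker selection, and a four-classifier reverse-validation
    harness (neural network, SVM, deep belief network, random forest).
    Includes a synthetic seed-image generator so the full pipeline is
    testable without proprietary photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    png,
    stats,
    utils,
    withr,
    nnet,
    e1071,
    randomForest,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
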