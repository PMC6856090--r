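Package: somnocam
Title: Contactless Sleep Analysis from Nocturnal Depth Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive sleep-medicine indices from nocturnal 3-D depth
    video of a sleeping person. Extracts a thoracic breathing-effort signal and
    a leg-motion signal from perspective-corrected depth frames, detects
    respiratory events as sustained drops of the breathing-signal envelope and
    periodic limb movements under AASM-style scoring rules, classifies 30-s
    epochs into sleep and wake with a boosted decision-tree ensemble trained
    under random undersampling of the majority class, and computes the
    device-agreement statistics (Pearson correlation, Bland-Altman, ROC with
    operating-point selection, event-level matching) used to validate a
    contactless device against reference polysomnography. A synthetic
    depth-video generator with known ground truth makes the whole pipeline
    testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
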