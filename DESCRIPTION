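Package: ufm
Title: Auditing Unique-Feature Memorisation in Neural-Network Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure whether a classifier has memorised a unique
    feature: a feature, such as a patient name rendered on a medical image,
    that occurs in exactly one training sample. Implements the M score (the
    mean change in predicted class probability between feature-injected and
    clean sample pairs) in white-box, grey-box and black-box privacy
    settings with one-tailed significance testing; a seed-deterministic
    training harness for small multilayer perceptrons and convolutional
    networks (Adam, cross-entropy, early stopping, dropout, weight decay,
    batch normalisation, data augmentation); synthetic data generators
    (a 3-D "two moons" task with a rare z-axis feature, procedural texture
    images, bitmap-font text patches); and multi-seed experiment drivers
    for memorisation frequency, training dynamics, concept-rarity
    comparisons, regularisation sweeps, pixel ablation and decision-boundary
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
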