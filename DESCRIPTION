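Package: budl
Title: Wrapper-Based Deep-Feature Selection for Breast Ultrasound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for wrapper-based selection of deep image features with
    binary population metaheuristics. Deep features extracted from the
    penultimate layer of pre-trained convolutional backbones (or generated
    synthetically with planted ground truth) are pruned by ten binary
    metaheuristic optimizers (MPA, GNDO, SMA, EO, MRFO, ASO, HHO, HGSO, PFA,
    PRO) minimizing a weighted cost that blends holdout SVM accuracy with the
    selected-feature ratio. Networks whose optimized accuracy clears a
    threshold are selected and their optimal features concatenated for a final
    classifier, as used in three-class (benign/malignant/normal) breast
    ultrasound lesion classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
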