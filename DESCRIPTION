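Package: carbcount
Title: Image-Based Carbohydrate Counting from Plate Geometry with
    Method-Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for automated carbohydrate counting from
    single annotated plate images: GrabCut-style foreground segmentation
    inside detector boxes, feedforward neural-network regression from
    geometric features (object area, bounding box, reference-spoon geometry,
    shooting angle) to portion weight, and nutrient computation against a
    food-composition table with exchange-unit conversion and per-piece
    carbohydrate rules. Includes a synthetic plate-scene generator with
    known ground-truth weights for training and validation, and the full
    set of method-agreement statistics used to compare estimators against
    measured values: RMSE, Pearson correlation, Lin's concordance
    correlation, paired t-test, Bland-Altman limits of agreement, and
    Dupont-Plummer paired sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
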