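Package: eddyscape
Title: Fine-Scale Plankton Imaging Transects: Segmentation, Classifier
    Post-Processing, Kriged Concentrations and Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing towed shadowgraph plankton-imaging transects
    across mesoscale ocean features. Covers the full desk-side pipeline: flat-field
    correction and k-harmonic-means segmentation of line-scan frames into organism
    vignettes; post-processing of convolutional-classifier output (fine-to-broad
    class mapping, confusion metrics, probability-threshold filtering to a target
    precision, precision/recall correction factors); conversion of classified
    vignettes to volume-normalised concentrations on 1-m depth strata and ordinary
    kriging onto a regular transect grid; water-mass delineation from ADCP velocity
    fields by k-means with distance-to-current, mixed-layer-depth and anomaly
    diagnostics; and driver attribution by water-mass ANOVA, random-forest
    regression with importance ranking, accumulated local effects, and predictor
    ablation. A synthetic-data module generates frames with planted organisms,
    classifier outputs with controllable confusion, and an eddy-in-boundary-current
    transect scenario with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
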