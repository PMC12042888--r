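Package: astromorph
Title: Single-Cell Astrocyte Morphometrics and Morphological Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape of segmented single-cell silhouettes (GFAP-labeled
    astrocytes and similar ramified cells) from 2-D binary masks. Computes fifteen
    morphometric descriptors per cell (area, perimeter, Feret diameter, moment-ellipse
    statistics, circularity, solidity, box-counting fractal dimension, gliding-box
    lacunarity, and relatives), measures dissimilarity between cell subpopulations with
    per-feature earth mover's distances aggregated into a correlation-corrected
    morphological distance, and runs a supervised protocol (center-weighted minority
    oversampling, one-vs-rest Random Forests over repeated stratified splits,
    permutation feature importance) to predict a cell's anatomical region or treatment
    condition. A synthetic branched-silhouette generator provides controllable test
    populations, and one-way ANOVA with Tukey post hoc tests covers classical inference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    randomForest,
    pracma,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
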