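# astromorph

Single-cell morphometrics for segmented astrocyte silhouettes: shape feature
extraction, a correlation-corrected population distance built on per-feature
earth mover's distances, and a supervised protocol for predicting a cell's
anatomical region or treatment condition from its shape.

## The problem

Astrocytes are highly ramified glial cells whose structure changes with
anatomical location and with experience (e.g. drug exposure). Given
already-segmented 2-D cell masks (maximum-projected, GFAP-labeled
silhouettes; segmentation itself is out of scope), the questions are:

* *How do we quantify one cell's shape?* — 15 morphometric descriptors per
  cell: area, filled area, equivalent-area diameter, max Feret diameter,
  eccentricity, perimeter, perimeter-to-surface ratio, sphericity (2-D
  circularity, 2√(πA)/P), spherical disproportion (its reciprocal), solidity,
  major/minor axis length, elongation (minor/major), box-counting fractal
  dimension, and gliding-box lacunarity.
* *How different are two cell populations?* — For each feature *k*, the 1-D
  earth mover's distance d(P\_m(k), P\_n(k)) between the two populations'
  empirical distributions (features min–max normalized on the pooled pair).
  These are aggregated into the **morphological distance**

  MD²(m, n) = dᵀ R d − ½ dᵀ |R − I| d,

  where R is the K×K Spearman correlation matrix of the features and |·| is
  elementwise: correlated features are discounted so redundant descriptors do
  not dominate. With fully decorrelated features (R = I) this reduces to the
  Euclidean norm of the EMD vector. Strong negative correlations can drive
  the raw MD² below zero; such entries are clamped to 0 and flagged.
* *Is shape predictive?* — One-vs-rest Random Forests over repeated
  stratified 70/30 splits, with center-weighted Gaussian minority
  oversampling (balance ratio 0.9, per-feature SD drawn from (0, σ₀/3)) on
  the training fold only, mean-decrease-in-accuracy (MDA) feature importance,
  and per-class sensitivity / precision / F1.

A synthetic silhouette generator (soma + recursively branching, tortuous
processes) provides fully controllable test populations, so every stage is
testable without the original imaging data. One-way ANOVA + Tukey HSD per
feature covers the classical inference companion.

## Worked example

```r
library(astromorph)

specs <- list(
  populationSpec(nCells = 30, params = silhouetteParams(branchProb = 0.05),
                 label = c(region = "core"),  seed = 1),
  populationSpec(nCells = 30, params = silhouetteParams(branchProb = 0.35),
                 label = c(region = "shell"), seed = 2))
ft <- generatePopulations(specs)
ft
#> FeatureTable: 60 cells x 15 features
#>   features: area, area_filled, equivalent_diameter_area, max_feret_diameter, eccentricity ...
#>   cellData: cell_id, image_id, region

mdMatrix(ft, "region")
#> MDMatrix over 'region' (2 groups)
#>        core shell
#> core  0.000 0.246
#> shell 0.246 0.000

repeatedEvaluate(ft, "region", splitScheme(repeats = 10, seed = 3))
#> ClassifierReport ('region', 10 repeats)
#>   accuracy: 98.89 ± 2.34% (majority baseline 50.00%)
#>   class sensitivity precision    f1 support
#> 1  core       1.000      0.98 0.989      30
#> 2 shell       0.978      1.00 0.988      30
```

The MD of 0.246 says the two populations are separated in morphological
space (identical populations give ≈ 0; the value is in pooled-normalized
feature units). The classifier recovers the planted difference in branching
almost perfectly — 98.89 ± 2.34% accuracy against a 50% majority baseline —
with sphericity-family and size features carrying the signal
(`mdaImportance(ft, "region")` ranks them).

Real data enter the same way through `masksFromLabels(readLabelImage(...))`
(TIFF/PNG label rasters, one positive integer per cell) plus a metadata CSV,
or through bounding-box annotations with `readViaAnnotations()` (VGG Image
Annotator JSON). `runPipeline()` (or the `inst/cli/astromorph` script) ties
features → distances → classification → ANOVA together and writes CSV/JSON
artifacts with a logged seed and config hash.

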