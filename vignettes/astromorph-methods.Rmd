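---
title: "Methods: single-cell morphometrics and the morphological distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell morphometrics and the morphological distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

# Scope and data model

`astromorph` quantifies the shape of individual segmented cells from 2-D
binary masks. The intended data are maximum-projected confocal stacks of
GFAP-immunolabeled astrocytes that have already been detected and segmented;
detection and segmentation are consumed, not performed. All geometry is
therefore 2-D, and "sphericity" is read as its planar analog, circularity
`2*sqrt(pi*A)/P`. Every mask is reduced to a single 8-connected foreground
component before analysis (`preprocessMask()`, policy `"largest"` by
default, `"strict"` to refuse fragmented input).

# The 15 morphometric descriptors

`computeFeatures()` returns, per cell: area; filled area; equivalent-area
diameter; maximum Feret diameter; eccentricity; perimeter;
perimeter-to-surface ratio; sphericity; spherical disproportion; solidity;
major and minor moment-ellipse axis lengths; elongation; box-counting
fractal dimension; gliding-box lacunarity. Conventions that differ between
toolkits are fixed as follows.

* **Units.** Everything is in pixels by default; `applyPixelSize = TRUE`
  converts length features by the mask's `pixelSize` (µm/pixel) and area
  features by its square. Dimensionless features are never scaled.
* **Feret diameter** is the maximum pairwise distance between foreground
  *pixel centers* (evaluated on convex-hull vertices; identical result,
  brute-force verifiable). A 1×5-pixel segment has Feret diameter 4.
* **Perimeter** uses the weighted boundary-step estimator of
  Benkrid & Crookes (the estimator scikit-image uses): border pixels are
  classified by their straight/diagonal border-neighbor configuration and
  weighted 1, √2 or (1+√2)/2. A pure Freeman chain with √2 diagonal weights
  overestimates a digitized circle's circumference by ≈5.5%; the
  configuration weights keep a radius-20 disk within 5% of circularity 1.
* **Moment ellipse.** Eccentricity and axis lengths come from the
  second-central-moment ellipse (axis length = 4√eigenvalue of the
  coordinate covariance, the common regionprops convention). Moments are
  computed from integer power sums on bounding-box coordinates, which makes
  them exact and hence bit-identical under translation and 90°/180°
  rotation. A single-pixel mask has no defined ellipse and is rejected
  (`DegenerateMaskError`).
* **Solidity** divides the pixel count by the *pixelized* convex hull area
  (pixel centers inside or on the hull polygon), which guarantees
  solidity ≤ 1; a polygonal hull area of pixel centers can be smaller than
  the pixel count and would push solidity above 1.
* **Holes** are retained everywhere except `area_filled`, so the
  `area_filled − area` difference isolates enclosed holes.
* **Elongation** is minor/major ∈ (0, 1]: bounded and interpretable.

## Fractal dimension and lacunarity

The box-counting dimension counts occupied boxes `N(s)` over dyadic box
sizes `s = 1, 2, 4, …` on the foreground bounding box, up to `max(h, w)/2`,
dropping the largest scale when fewer than 4 boxes tile the box (saturation
bias); at least 3 scales are required (`InsufficientScalesError` otherwise,
and `computeFeatures()` degrades to `NA` with a warning on masks that small).
The dimension is the negative least-squares slope of `log N` vs `log s`.
`N(s)` is the minimum over the four corner anchorings of the grid — the
minimal-cover reading of box counting — which removes grid-placement bias
and makes the value *exactly* invariant under 90°/180° rotation. Reference
sets hit their theoretical values: a filled square gives 2, a one-pixel line
1, a depth-6 Sierpinski triangle log 3/log 2 ≈ 1.585 (exactly, because the
dyadic grids align).

Lacunarity uses box masses `M` over the non-overlapping `r × r` tiling
(partial edge boxes discarded) at dyadic `r = 2, 4, …, min(h, w)/4`:
`Λ(r) = ⟨M²⟩/⟨M⟩²`, averaged over the four grid anchorings (rotation
exactness again) and then over scales. `Λ = 1` for homogeneous mass,
`Λ ≥ 1` always (Jensen), and a half-full/half-empty tiling gives exactly 2.
No single convention for lacunarity's window scheme, scale set or
aggregation is standard; stride-`r` tiling with a dyadic scale ladder and a
plain mean was chosen once for its exact small-case arithmetic and is not a
tuning knob.

## Invariances, and one caveat

All 15 features are bit-identical under 90°/180° rotation and across
repeated runs (no randomness anywhere in extraction). Under *resolution*
rescaling — digitizing the same continuous shape on a grid `s` times finer —
area scales as `s²`, perimeter and Feret as `s`, and dimensionless features
are stable within 5%. Under *pixel replication* area is exactly `s²`-fold
and calipers scale, but the perimeter does not: replication preserves
staircase jaggedness at scale, and a boundary-step estimator correctly
measures that longer boundary. Scale-equivariance claims for
perimeter-derived features therefore only make sense for resolution
rescaling, and that is what the tests assert.

# Population distance

For two groups, features are min–max normalized to [0, 1] on the pooled
pair (so features are commensurate; constant features map to 0 with a
warning and contribute nothing), then for each feature the exact 1-D earth
mover's distance between the empirical distributions is computed as the area
between empirical CDFs. The per-feature distances `d` are aggregated as

`MD² = dᵀ R d − ½ dᵀ |R − I| d`

with `R` the Spearman matrix (average ranks on ties) of the pooled pair —
the population defining `R` is not otherwise determined, and pooling the two
groups under comparison is the symmetric choice. Undefined correlations from
constant features are set to 0: their `d` component is 0, so they cannot
contribute either way.

The quadratic form is *not* positive semidefinite. The feature set contains
exactly anticorrelated pairs (sphericity and its reciprocal have Spearman
−1), and for such a pair the form contributes `(d_i − d_j)² − d_i d_j`,
which is negative whenever the two distances are similar. Raw `MD² < 0` is
clamped to 0, flagged in the `MDMatrix`, and warned about — the clamp
preserves the nonnegativity contract while exposing the event rather than
hiding it. A practical consequence: when *every* feature shifts by a similar
normalized amount, the EMD vector points along the uniform direction, which
lies in the form's negative cone, and MD collapses to 0. MD is most
informative when populations differ in a subset of features, which is the
regime the generator-based recovery tests exercise.

Signed EMD heatmaps (`signedEmdVector()`, `signedEmdTable()`) attach the
sign of the *median* shift (group2 − group1) to each distance; medians, not
means, because several features are strongly skewed.

# Supervised protocol

Class imbalance is handled by a center-weighted Gaussian oversampler:
synthetic minority points are the class centroid plus a Gaussian
displacement whose per-feature SD is drawn uniformly from
`(0, σ₀ · sdMaxFraction)` with `σ₀` the class SD, so density is highest near
the centroid and the expanded data are not pushed toward the class margins.
Defaults: balance ratio 0.9 (minority topped up to 90% of the majority
count), `sdMaxFraction = 1/3`. Classical SMOTE-style interpolation between
neighbors is deliberately not the default; the centered variant is the
described behavior this package implements. Originals are never altered.

Classification is one-vs-rest: one Random Forest (500 trees, √K features
per split, unlimited depth — conventional forest defaults, configurable) per
class, test labels by highest positive-class vote fraction, ties broken by a
seed-shuffled class order. Evaluation (`repeatedEvaluate()`) repeats a
stratified 70/30 split 10 times by default; stratification is used so small
classes appear in every fold. Oversampling is applied to the *training fold
only* — the alternative (oversampling before splitting) leaks synthetic
copies of test-adjacent points into training and inflates accuracy.
Reported: per-repeat accuracies, mean ± SD (printed to two decimals),
per-class sensitivity/precision/F1 averaged over repeats (per-class
"accuracy" is reported as recall, the less ambiguous reading), a pooled
confusion matrix, and a majority-vote baseline.

MDA importance neutralizes one feature at a time. The default permutes the
feature on the held-out fold and reuses the fitted ensemble; the exact
remove-and-retrain reading is available as `mode = "retrain"` (K+1 fits per
repeat instead of one). Both average the accuracy drop over repeats; ties
rank alphabetically for determinism. Metrics with zero denominators
(`binaryMetrics()`) are `NA`, never silently 0.

All stochastic steps derive child seeds from the scheme/config seeds, so a
report is bit-reproducible from `(seed, scheme, config)`.

# Classical inference

`anovaTukey()` runs a per-feature one-way ANOVA (base R `aov`) on the raw,
unnormalized features and, wherever the null is rejected at α = 0.05,
Tukey's HSD over all group pairs. Cells are treated as independent
observations — the companion `animal_id` annotation is preserved so users
can aggregate to animal level first if they prefer a nested analysis. A
feature with zero variance everywhere has an undefined F (0/0) and is
reported as `NA`. Calibration: over 2,000 simulated null datasets (3 groups
× 10 cells), the empirical type-I rate at α = 0.05 stays within 0.05 ± 0.02
(checked in the acceptance suite).

# The synthetic generator

`generateMask()` draws a disk soma (radius ~ N(12, 2) px on a 256² raster by
default) and grows `nPrimary = 6` processes as chains of thick segments
(length ~ N(18, 6) px, angular jitter SD 0.3 rad, width 3 px tapering by
0.85 per branching level); each segment ends in a bifurcation with
probability `branchProb = 0.15` or continues with probability 0.8, to depth
6. These defaults were set once to resemble GFAP-filled astrocyte
silhouettes at ≈0.57 µm/px — soma ≈ 7 µm radius, arbor spanning
≈ 60–120 µm — and are not adjusted against test outcomes. The construction
guarantees a single 8-connected component and is deterministic per seed
(≈ 40 ms per cell including feature extraction, so population studies are
desk-scale).

What the generator emulates: a bright central soma, ramified tortuous
processes, controllable branching/size statistics, populations that differ
in prescribed parameters. What it does not: fluorescence noise, PSF blur,
segmentation errors, touching cells, intensity heterogeneity, 3-D structure.
Passing recovery tests therefore demonstrate that the *pipeline* responds
correctly to controlled shape differences — not that real astrocyte
segmentations are error-free or that the published biological effect sizes
are reproduced (the original imaging data are not deposited, and the
published accuracies are out of the package's acceptance surface).

The feature-distribution mode of `populationSpec()` bypasses rasterization:
feature vectors are drawn from prescribed marginal quantile functions
coupled by a Gaussian copula calibrated to a target Spearman matrix
(`pearson = 2 sin(π ρ_s / 6)` per entry). It exists so the distance and
classification modules can be tested against *exactly known* distributions:
e.g. "populations separated by 3 SD" is exact there, whereas a 3-SD shift in
a generator *parameter* (mean segment length) measurably induces only ≈2 SD
of separation in feature space — the generator's other variability
(branching, tortuosity) dilutes it.

# Problem sizes and numerical choices in the test suite

The recovery simulations use 50–80 cells per population on 192² rasters
(MD monotonicity across 1/2/3-SD segment-length separations), 150 cells per
class in feature-distribution mode for the ≥90% separability check, 10
shuffled-label seeds pooled into one binomial interval around 1/3, 500
random sample pairs (sizes ≤ 8) against an exact sorted-transport oracle for
the EMD, and 2,000 null ANOVA datasets. These sizes are the package's own
balance between statistical resolution and a test suite that runs in a
couple of minutes on one CPU.

# Known limitations

* The MD quadratic form is indefinite (see above); clamped zeros are
  flagged, but comparisons between clamped entries carry no information.
* Boundary-step perimeters are digitization-dependent; compare perimeters
  only across images of equal resolution, or convert with `pixelSize` and
  equal optics.
* Eccentricity reaches 1 and elongation 0 for exactly collinear masks;
  such degenerate silhouettes are not rejected (only 1-pixel masks are).
* Cells are treated as exchangeable; animal-level clustering is the user's
  responsibility via `animal_id`.
* PNG label rasters are assumed 8-bit; use TIFF for more than 255 cells per
  image.
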