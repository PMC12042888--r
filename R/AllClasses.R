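#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov cor dist median na.omit quantile rnorm runif sd TukeyHSD
#'   pnorm setNames predict var
#' @importFrom utils read.csv write.csv head
NULL

#' CellMask: one segmented cell as a 2-D boolean raster
#'
#' Container for a single segmented cell silhouette (e.g. one GFAP-labeled
#' astrocyte cut out of a labeled segmentation raster). The raster is stored
#' as a logical matrix in image orientation (rows = y, columns = x).
#'
#' @slot pixels logical matrix; `TRUE` marks foreground.
#' @slot pixelSize physical side length of one pixel (micrometres per pixel);
#'   purely metadata until lengths are converted, default 1.
#' @slot cellId,imageId identifier strings.
#' @slot labels named character vector of categorical annotations; any subset
#'   of `region`, `treatment`, `reward`, `sex`, `animal_id` (others allowed).
#'
#' @seealso [CellMask()], [preprocessMask()], [computeFeatures()]
#' @export
setClass("CellMask",
  slots = c(
    pixels = "matrix",
    pixelSize = "numeric",
    cellId = "character",
    imageId = "character",
    labels = "character"
  )
)

setValidity("CellMask", function(object) {
  px <- object@pixels
  if (!is.logical(px)) return("'pixels' must be a logical matrix")
  if (nrow(px) < 3L || ncol(px) < 3L) return("raster dimensions must be at least 3x3")
  if (!any(px)) return("mask has no foreground pixel")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("'pixelSize' must be a positive scalar")
  if (length(object@cellId) != 1L || length(object@imageId) != 1L)
    return("'cellId' and 'imageId' must be single strings")
  TRUE
})

#' FeatureTable: cells-by-features morphometric matrix with labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one `"features"`
#' assay with morphometric features in rows and cells in columns, and per-cell
#' annotations (`cell_id`, `image_id`, `region`, `treatment`, ...) in
#' `colData`. All population-level analysis (EMD, morphological distance,
#' classification, ANOVA) consumes this class.
#'
#' @seealso [FeatureTable()], [featureMatrix()], [computeFeatureTable()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'features' assay")
  a <- SummarizedExperiment::assay(object, "features")
  if (!is.numeric(a)) return("'features' assay must be numeric")
  if (anyNA(a)) return("'features' assay must not contain missing values")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("feature names must be present and unique")
  TRUE
})

#' EMDVector: per-feature earth mover's distances between two groups
#'
#' @slot d nonnegative numeric vector, one 1-D earth mover's distance per
#'   feature (group order is irrelevant to `d`).
#' @slot sign integer in -1/0/+1 per feature: sign of
#'   `median(group2) - median(group1)`.
#' @slot groups the two group labels compared, `c(group1, group2)`.
#' @seealso [signedEmdVector()], [morphologicalDistance()]
#' @export
setClass("EMDVector",
  slots = c(d = "numeric", sign = "integer", groups = "character"))

setValidity("EMDVector", function(object) {
  if (any(object@d < 0)) return("EMD components must be nonnegative")
  if (length(object@sign) != length(object@d)) return("'sign' length must match 'd'")
  if (!all(object@sign %in% c(-1L, 0L, 1L))) return("'sign' entries must be -1, 0 or +1")
  if (length(object@groups) != 2L) return("'groups' must name the two groups")
  TRUE
})

#' MDMatrix: pairwise morphological distances between groups
#'
#' @slot values symmetric nonnegative matrix of morphological distances with a
#'   zero diagonal, rows/columns named by group.
#' @slot clampFlags logical matrix of the same shape; `TRUE` marks entries
#'   whose raw squared distance was negative and clamped to zero.
#' @slot grouping name of the label column the groups came from.
#' @seealso [mdMatrix()]
#' @export
setClass("MDMatrix",
  slots = c(values = "matrix", clampFlags = "matrix", grouping = "character"))

setValidity("MDMatrix", function(object) {
  v <- object@values
  if (!isTRUE(all.equal(v, t(v)))) return("MD matrix must be symmetric")
  if (any(v < 0)) return("MD values must be nonnegative")
  if (any(abs(diag(v)) > 1e-12)) return("MD diagonal must be zero")
  if (!identical(dim(v), dim(object@clampFlags)))
    return("'clampFlags' must match the shape of 'values'")
  TRUE
})

#' OversamplerConfig: center-weighted minority oversampling settings
#'
#' Minority classes are augmented with synthetic points placed at the class
#' centroid plus Gaussian displacement whose per-feature SD is drawn uniformly
#' from `(0, sd0 * sdMaxFraction)`, `sd0` being the per-feature SD of the
#' minority class, so synthetic density is highest near the centroid.
#'
#' @slot balanceRatio target minority/majority count ratio in (0, 1], default 0.9.
#' @slot sdMaxFraction upper end of the SD draw as a fraction of the class SD,
#'   default 1/3.
#' @slot seed integer RNG seed.
#' @seealso [oversamplerConfig()], [oversample()]
#' @export
setClass("OversamplerConfig",
  slots = c(balanceRatio = "numeric", sdMaxFraction = "numeric", seed = "integer"))

setValidity("OversamplerConfig", function(object) {
  if (object@balanceRatio <= 0 || object@balanceRatio > 1)
    return("'balanceRatio' must be in (0, 1]")
  if (object@sdMaxFraction <= 0) return("'sdMaxFraction' must be positive")
  TRUE
})

#' SplitScheme: repeated train/test evaluation settings
#'
#' @slot trainFraction fraction of cells assigned to training, default 0.7.
#' @slot repeats number of random splits averaged over, default 10.
#' @slot seed integer RNG seed.
#' @slot stratified stratify splits by class (default `TRUE`) so every class
#'   appears in every test fold.
#' @seealso [splitScheme()], [repeatedEvaluate()]
#' @export
setClass("SplitScheme",
  slots = c(trainFraction = "numeric", repeats = "integer", seed = "integer",
            stratified = "logical"))

setValidity("SplitScheme", function(object) {
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("'trainFraction' must be in (0, 1)")
  if (object@repeats < 1L) return("'repeats' must be at least 1")
  TRUE
})

#' ClassifierReport: results of the repeated one-vs-rest evaluation
#'
#' @slot accuracies per-repeat test accuracies (length = number of repeats).
#' @slot baselineAccuracies per-repeat accuracies of the majority-vote baseline.
#' @slot classMetrics data.frame of per-class sensitivity, precision, F1 and
#'   support, averaged over repeats.
#' @slot confusion pooled confusion matrix (rows = truth, columns = predicted).
#' @slot importance named numeric of permutation (MDA) feature importances, or
#'   length-0 when not requested.
#' @slot grouping label column that was predicted.
#' @seealso [repeatedEvaluate()], [mdaImportance()]
#' @export
setClass("ClassifierReport",
  slots = c(accuracies = "numeric", baselineAccuracies = "numeric",
            classMetrics = "data.frame", confusion = "matrix",
            importance = "numeric", grouping = "character"))

#' AnovaTukeyResult: per-feature one-way ANOVA with Tukey post hoc tests
#'
#' @slot anova data.frame with one row per feature: `feature`, `F`, `p`, `stars`.
#' @slot tukey data.frame with one row per feature x group pair for features
#'   whose ANOVA rejected at `alpha`: `feature`, `comparison`, `diff`, `p_adj`,
#'   `stars`.
#' @slot alpha rejection level gating the post hoc tests.
#' @seealso [anovaTukey()]
#' @export
setClass("AnovaTukeyResult",
  slots = c(anova = "data.frame", tukey = "data.frame", alpha = "numeric"))

#' SilhouetteParams: generative settings for one branched silhouette
#'
#' Parameters of the synthetic silhouette generator: a central disk soma with
#' `nPrimary` primary processes grown as tortuous, recursively bifurcating
#' chains of thick segments (a stochastic L-system). Means/SDs are in pixels,
#' angles in radians.
#'
#' @slot imageSize raster side length (square raster).
#' @slot somaRadius `c(mean, sd)` of the soma radius.
#' @slot nPrimary number of primary processes leaving the soma.
#' @slot branchProb probability that a segment ends in a bifurcation.
#' @slot segmentLength `c(mean, sd)` of segment length.
#' @slot tortuosity SD of the angular jitter added per segment.
#' @slot thickness process width at the soma (tapered with depth).
#' @slot seed integer RNG seed.
#' @seealso [silhouetteParams()], [generateMask()]
#' @export
setClass("SilhouetteParams",
  slots = c(imageSize = "integer", somaRadius = "numeric", nPrimary = "integer",
            branchProb = "numeric", segmentLength = "numeric",
            tortuosity = "numeric", thickness = "numeric", seed = "integer"))

setValidity("SilhouetteParams", function(object) {
  if (object@imageSize < 16L) return("'imageSize' must be at least 16")
  if (object@somaRadius[1] <= 0) return("mean soma radius must be positive")
  if (object@branchProb < 0 || object@branchProb > 1)
    return("'branchProb' must be in [0, 1]")
  if (object@segmentLength[1] <= 0) return("mean segment length must be positive")
  if (object@thickness <= 0) return("'thickness' must be positive")
  TRUE
})

#' PopulationSpec: a group of synthetic cells
#'
#' Either mask mode (default): `nCells` silhouettes are generated from
#' `params` and pushed through feature extraction; or feature-distribution
#' mode: feature vectors are sampled directly from prescribed marginal
#' quantile functions coupled by a Gaussian copula calibrated to a target
#' Spearman matrix, so downstream modules can be tested against exactly known
#' distributions independent of the morphometry stage.
#'
#' @slot label named character vector of annotations attached to every cell
#'   (e.g. `c(region = "AC")`).
#' @slot nCells number of cells.
#' @slot params [SilhouetteParams] used in mask mode.
#' @slot marginals in feature-distribution mode, a named list of quantile
#'   functions (one per feature); empty list selects mask mode.
#' @slot spearman target Spearman correlation matrix for feature-distribution
#'   mode, or `NULL` for independent features.
#' @slot seed integer RNG seed.
#' @seealso [populationSpec()], [generatePopulation()]
#' @export
setClass("PopulationSpec",
  slots = c(label = "character", nCells = "integer", params = "SilhouetteParams",
            marginals = "list", spearman = "ANY", seed = "integer"))

setValidity("PopulationSpec", function(object) {
  if (object@nCells < 2L) return("'nCells' must be at least 2")
  if (is.null(names(object@label)) && length(object@label))
    return("'label' must be a named character vector")
  if (length(object@marginals)) {
    if (is.null(names(object@marginals)) || !all(vapply(object@marginals, is.function, TRUE)))
      return("'marginals' must be a named list of quantile functions")
    if (!is.null(object@spearman)) {
      s <- object@spearman
      if (!is.matrix(s) || nrow(s) != length(object@marginals) ||
          !isTRUE(all.equal(s, t(s))))
        return("'spearman' must be a symmetric matrix matching 'marginals'")
    }
  }
  TRUE
})
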