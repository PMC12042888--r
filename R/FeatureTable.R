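#' Construct a FeatureTable
#'
#' @param features numeric matrix or data.frame of cells (rows) by features
#'   (columns), column names = feature names.
#' @param cellData data.frame (or DataFrame) of per-cell annotations, one row
#'   per cell; typically `cell_id`, `image_id` and label columns such as
#'   `region` or `treatment`.
#' @return A [FeatureTable-class].
#' @examples
#' x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("area", "perimeter")))
#' ft <- FeatureTable(x, data.frame(region = rep(c("AC", "PC"), 5)))
#' ft
#' @export
FeatureTable <- function(features, cellData = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    .amStop("SchemaError", "'features' must have feature column names")
  if (is.null(cellData))
    cellData <- S4Vectors::DataFrame(row.names = seq_len(nrow(features)))
  cellData <- S4Vectors::DataFrame(cellData)
  if (nrow(cellData) != nrow(features))
    .amStop("SchemaError", "cellData rows (%d) must match cells (%d)",
            nrow(cellData), nrow(features))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)), colData = cellData)
  new("FeatureTable", se)
}

#' @describeIn FeatureTable numeric matrix of cells (rows) by features (columns).
#' @param x a `FeatureTable`.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @describeIn FeatureTable per-cell annotation DataFrame.
#' @export
cellData <- function(x) SummarizedExperiment::colData(x)

#' @describeIn FeatureTable a label column as a character vector.
#' @param column name of the label column.
#' @export
groupLabels <- function(x, column) {
  cd <- SummarizedExperiment::colData(x)
  if (!column %in% colnames(cd))
    .amStop("SchemaError", "label column '%s' not present in cellData", column)
  as.character(cd[[column]])
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d cells x %d features\n",
              ncol(object), nrow(object)))
  cat("  features:", paste(head(rownames(object), 5), collapse = ", "),
      if (nrow(object) > 5) "...\n" else "\n")
  lab <- colnames(SummarizedExperiment::colData(object))
  if (length(lab)) cat("  cellData:", paste(lab, collapse = ", "), "\n")
})

#' Combine FeatureTables over cells
#'
#' @param ... `FeatureTable`s sharing the same feature set.
#' @return A single [FeatureTable-class] with cells concatenated.
#' @export
combineFeatureTables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is(tabs[[1]], "FeatureTable"))
    tabs <- tabs[[1]]
  feats <- lapply(tabs, featureMatrix)
  nm <- colnames(feats[[1]])
  if (!all(vapply(feats, function(f) identical(colnames(f), nm), TRUE)))
    .amStop("SchemaError", "feature sets differ between tables")
  cds <- lapply(tabs, function(t) as.data.frame(cellData(t)))
  allCols <- unique(unlist(lapply(cds, colnames)))
  cds <- lapply(cds, function(d) {
    for (cc in setdiff(allCols, colnames(d))) d[[cc]] <- NA
    d[, allCols, drop = FALSE]
  })
  FeatureTable(do.call(rbind, feats), do.call(rbind, cds))
}

#' Subset a FeatureTable to cells with given labels
#'
#' @param x a [FeatureTable-class].
#' @param column label column name.
#' @param groups character vector of labels to keep; all must occur.
#' @return The subset `FeatureTable`.
#' @export
subsetGroups <- function(x, column, groups) {
  lab <- groupLabels(x, column)
  missing <- setdiff(groups, lab)
  if (length(missing))
    .amStop("LabelError", "unknown group label(s): %s",
            paste(missing, collapse = ", "))
  x[, lab %in% groups]
}

#' Min-max normalize features to [0, 1]
#'
#' Each feature is scaled by its pooled minimum and maximum over all cells in
#' the table (call on the pooled pair of groups being compared so both share
#' one dynamic range). Constant features map to 0 with a warning.
#'
#' @param table a [FeatureTable-class] with at least 2 cells.
#' @return The normalized `FeatureTable`.
#' @export
normalizeFeatures <- function(table) {
  f <- featureMatrix(table)
  if (nrow(f) < 2L)
    .amStop("InsufficientSampleError", "normalization needs at least 2 cells")
  rng <- apply(f, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span <= 0
  if (any(const))
    .amWarn("ConstantFeatureWarning",
            "constant feature(s) mapped to 0: %s",
            paste(colnames(f)[const], collapse = ", "))
  span[const] <- 1
  g <- sweep(sweep(f, 2, rng[1, ]), 2, span, "/")
  g[, const] <- 0
  FeatureTable(g, cellData(table))
}

#' Extract features from a list of cell masks
#'
#' Runs [computeFeatures()] on each mask and assembles the results, together
#' with each mask's identifiers and labels, into a [FeatureTable-class].
#'
#' @param masks list of [CellMask-class] objects.
#' @param applyPixelSize passed to [computeFeatures()].
#' @return A [FeatureTable-class] with columns `cell_id`, `image_id` and any
#'   mask labels in `cellData`.
#' @export
computeFeatureTable <- function(masks, applyPixelSize = FALSE) {
  if (!length(masks)) .amStop("EmptyMaskError", "no masks supplied")
  feats <- t(vapply(masks, computeFeatures, numeric(15),
                    applyPixelSize = applyPixelSize))
  labNames <- unique(unlist(lapply(masks, function(m) names(m@labels))))
  cd <- data.frame(
    cell_id = vapply(masks, cellId, ""),
    image_id = vapply(masks, function(m) m@imageId, ""),
    stringsAsFactors = FALSE
  )
  for (ln in labNames)
    cd[[ln]] <- vapply(masks, function(m)
      if (ln %in% names(m@labels)) unname(m@labels[[ln]]) else NA_character_, "")
  FeatureTable(feats, cd)
}

#' Read / write a feature table as CSV
#'
#' The CSV has one row per cell; non-feature columns are kept as cell
#' annotations. `writeFeatureTable` writes annotations first, then the
#' features, in [morphometricFeatureNames()] order where applicable.
#'
#' @param path CSV file path.
#' @param featureColumns which columns are features; defaults to the
#'   intersection with [morphometricFeatureNames()], or all numeric columns if
#'   that intersection is empty.
#' @return `readFeatureTable`: a [FeatureTable-class]; `writeFeatureTable`:
#'   the path, invisibly.
#' @export
readFeatureTable <- function(path, featureColumns = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(featureColumns)) {
    featureColumns <- intersect(morphometricFeatureNames(), colnames(df))
    if (!length(featureColumns))
      featureColumns <- colnames(df)[vapply(df, is.numeric, TRUE)]
  }
  missing <- setdiff(featureColumns, colnames(df))
  if (length(missing))
    .amStop("SchemaError", "feature column(s) absent from %s: %s", path,
            paste(missing, collapse = ", "))
  FeatureTable(as.matrix(df[, featureColumns, drop = FALSE]),
               df[, setdiff(colnames(df), featureColumns), drop = FALSE])
}

#' @rdname readFeatureTable
#' @param table a [FeatureTable-class].
#' @export
writeFeatureTable <- function(table, path) {
  df <- cbind(as.data.frame(cellData(table)),
              as.data.frame(featureMatrix(table)))
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
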