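#' 1-D earth mover's distance between two empirical distributions
#'
#' The 1-Wasserstein distance between the empirical distributions of two
#' samples, computed exactly as the area between their empirical CDFs,
#' `integral |F_a - F_b|`. For equal sample sizes this equals the mean
#' absolute difference of the sorted samples; it is the minimal transport cost
#' for moving one empirical distribution onto the other.
#'
#' @param a,b non-empty numeric sample vectors (sizes may differ).
#' @return Nonnegative scalar distance, in the units of the feature.
#' @examples
#' emd1d(c(0, 1), c(1, 2))  # translation by 1
#' @export
emd1d <- function(a, b) {
  if (!length(a) || !length(b))
    .amStop("EmptySampleError", "both samples must be non-empty")
  if (anyNA(a) || anyNA(b))
    .amStop("EmptySampleError", "samples must not contain NA")
  v <- sort(unique(c(a, b)))
  if (length(v) == 1L) return(0)
  Fa <- stats::ecdf(a)(v)
  Fb <- stats::ecdf(b)(v)
  k <- length(v)
  sum(abs(Fa[-k] - Fb[-k]) * diff(v))
}

#' Per-feature signed EMD vector between two cell groups
#'
#' For each feature, the earth mover's distance between the two groups'
#' empirical distributions, plus the sign of the median shift
#' (`group2 - group1`) used to orient heatmaps (blue = decreased median,
#' red = increased median). By default features are first min-max normalized
#' on the pooled pair of groups so distances are commensurate across features.
#'
#' @param table a [FeatureTable-class].
#' @param grouping label column name.
#' @param group1,group2 the two group labels (each with >= 2 cells).
#' @param normalize pool-normalize features to [0, 1] first (default `TRUE`).
#' @return An [EMDVector-class].
#' @export
signedEmdVector <- function(table, grouping, group1, group2, normalize = TRUE) {
  pooled <- subsetGroups(table, grouping, c(group1, group2))
  lab <- groupLabels(pooled, grouping)
  if (sum(lab == group1) < 2L || sum(lab == group2) < 2L)
    .amStop("InsufficientSampleError", "both groups need at least 2 cells")
  if (normalize)
    pooled <- withCallingHandlers(normalizeFeatures(pooled),
      ConstantFeatureWarning = function(w) invokeRestart("muffleWarning"))
  f <- featureMatrix(pooled)
  f1 <- f[lab == group1, , drop = FALSE]
  f2 <- f[lab == group2, , drop = FALSE]
  d <- vapply(seq_len(ncol(f)), function(k) emd1d(f1[, k], f2[, k]), 1.0)
  sg <- as.integer(sign(apply(f2, 2, median) - apply(f1, 2, median)))
  new("EMDVector", d = setNames(d, colnames(f)), sign = sg,
      groups = c(group1, group2))
}

#' Spearman correlation matrix of the features
#'
#' Pairwise Spearman rank correlation (average ranks for ties) over the cells
#' of the table; call on the pooled union of the two groups under comparison.
#' Correlations that are undefined because a feature is constant are set to 0
#' (such features have zero EMD and cannot contribute to the distance).
#'
#' @param table a [FeatureTable-class] with at least 3 cells.
#' @return Symmetric K x K correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(table) {
  f <- featureMatrix(table)
  if (nrow(f) < 3L)
    .amStop("InsufficientSampleError",
            "Spearman matrix needs at least 3 cells (got %d)", nrow(f))
  R <- suppressWarnings(cor(f, method = "spearman"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

#' Correlation-corrected morphological distance
#'
#' Aggregates a per-feature EMD vector `d` into a single population distance
#' while discounting redundant (correlated) features:
#' `MD^2 = d' R d - (1/2) d' |R - I| d`, with `R` the features' Spearman
#' matrix and `|.|` elementwise. When `R = I` this reduces to the Euclidean
#' norm of `d`, so all features contribute equally. Strong negative
#' correlations can drive the raw `MD^2` below zero; the value is then clamped
#' to 0, flagged, and a warning is issued.
#'
#' @param d an [EMDVector-class] or nonnegative numeric vector.
#' @param R correlation matrix of matching dimension.
#' @return Nonnegative scalar MD with attribute `clamped` (logical).
#' @examples
#' morphologicalDistance(c(3, 4), diag(2))  # 5
#' @export
morphologicalDistance <- function(d, R) {
  if (is(d, "EMDVector")) d <- d@d
  d <- as.numeric(d)
  K <- length(d)
  if (!is.matrix(R) || nrow(R) != K || ncol(R) != K)
    .amStop("DimensionError",
            "R must be a %d x %d matrix to match the EMD vector", K, K)
  md2 <- drop(t(d) %*% R %*% d) - 0.5 * drop(t(d) %*% abs(R - diag(K)) %*% d)
  clamped <- md2 < 0
  if (clamped)
    .amWarn("NegativeMD2Warning",
            "raw MD^2 = %.6g < 0 under negative feature correlations; clamped to 0",
            md2)
  structure(sqrt(max(0, md2)), clamped = clamped)
}

#' Pairwise morphological distance matrix between groups
#'
#' For every pair of groups in the label column, features are min-max
#' normalized on that pooled pair, the per-feature EMD vector and pooled
#' Spearman matrix are computed, and [morphologicalDistance()] is evaluated.
#'
#' @param table a [FeatureTable-class].
#' @param grouping label column name; needs >= 2 groups with >= 2 cells each.
#' @param normalize pool-normalize each pair before EMD (default `TRUE`).
#' @return An [MDMatrix-class].
#' @export
mdMatrix <- function(table, grouping, normalize = TRUE) {
  lab <- groupLabels(table, grouping)
  groups <- sort(unique(lab))
  if (length(groups) < 2L)
    .amStop("InsufficientSampleError", "need at least 2 groups")
  small <- groups[table(factor(lab, groups)) < 2L]
  if (length(small))
    .amStop("InsufficientSampleError", "group(s) with < 2 cells: %s",
            paste(small, collapse = ", "))
  G <- length(groups)
  vals <- matrix(0, G, G, dimnames = list(groups, groups))
  flags <- matrix(FALSE, G, G, dimnames = list(groups, groups))
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    pooled <- subsetGroups(table, grouping, groups[c(i, j)])
    if (normalize)
      pooled <- withCallingHandlers(normalizeFeatures(pooled),
        ConstantFeatureWarning = function(w) invokeRestart("muffleWarning"))
    ev <- signedEmdVector(pooled, grouping, groups[i], groups[j],
                          normalize = FALSE)
    R <- spearmanMatrix(pooled)
    md <- withCallingHandlers(morphologicalDistance(ev, R),
      NegativeMD2Warning = function(w) invokeRestart("muffleWarning"))
    vals[i, j] <- vals[j, i] <- as.numeric(md)
    flags[i, j] <- flags[j, i] <- attr(md, "clamped")
  }
  if (any(flags))
    .amWarn("NegativeMD2Warning",
            "%d group pair(s) had negative raw MD^2 clamped to 0", sum(flags) / 2)
  new("MDMatrix", values = vals, clampFlags = flags, grouping = grouping)
}

#' @describeIn mdMatrix distance values as a plain matrix.
#' @param x an `MDMatrix`.
#' @export
mdValues <- function(x) x@values

#' @describeIn mdMatrix logical matrix of clamped entries.
#' @export
clampFlags <- function(x) x@clampFlags

setMethod("show", "MDMatrix", function(object) {
  cat(sprintf("MDMatrix over '%s' (%d groups)\n", object@grouping,
              nrow(object@values)))
  print(round(object@values, 3))
  if (any(object@clampFlags))
    cat("  note:", sum(object@clampFlags) / 2, "pair(s) clamped at 0\n")
})

#' Signed EMD heatmap table across group comparisons
#'
#' Convenience builder for the features x comparisons signed-EMD table used in
#' heatmaps: each column is `sign * d` for one ordered group comparison.
#'
#' @param table a [FeatureTable-class].
#' @param grouping label column name.
#' @param comparisons list of `c(group1, group2)` pairs; default all unordered
#'   pairs in sorted label order.
#' @param normalize pool-normalize each pair (default `TRUE`).
#' @return data.frame with one row per feature and one column per comparison
#'   (named `"g2 vs g1"`), entries = signed EMD.
#' @export
signedEmdTable <- function(table, grouping, comparisons = NULL, normalize = TRUE) {
  if (is.null(comparisons)) {
    groups <- sort(unique(groupLabels(table, grouping)))
    comparisons <- list()
    for (i in seq_along(groups)) for (j in seq_along(groups))
      if (i < j) comparisons[[length(comparisons) + 1L]] <- groups[c(i, j)]
  }
  cols <- lapply(comparisons, function(pr) {
    ev <- signedEmdVector(table, grouping, pr[1], pr[2], normalize = normalize)
    ev@sign * ev@d
  })
  out <- as.data.frame(cols, optional = TRUE)
  colnames(out) <- vapply(comparisons, function(pr)
    paste(pr[2], "vs", pr[1]), "")
  out
}
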