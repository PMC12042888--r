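#' Oversampler configuration
#'
#' @param balanceRatio target minority/majority count ratio in (0, 1].
#' @param sdMaxFraction upper end of the per-feature SD draw, as a fraction of
#'   the minority class SD.
#' @param seed integer RNG seed.
#' @return An [OversamplerConfig-class].
#' @export
oversamplerConfig <- function(balanceRatio = 0.9, sdMaxFraction = 1 / 3, seed = 1L) {
  new("OversamplerConfig", balanceRatio = balanceRatio,
      sdMaxFraction = sdMaxFraction, seed = as.integer(seed))
}

#' Split scheme for repeated evaluation
#'
#' @param trainFraction fraction of cells used for training.
#' @param repeats number of random splits.
#' @param seed integer RNG seed.
#' @param stratified stratify the split by class.
#' @return A [SplitScheme-class].
#' @export
splitScheme <- function(trainFraction = 0.7, repeats = 10L, seed = 1L,
                        stratified = TRUE) {
  new("SplitScheme", trainFraction = trainFraction,
      repeats = as.integer(repeats), seed = as.integer(seed),
      stratified = stratified)
}

#' Center-weighted minority oversampling
#'
#' Augments each minority class with synthetic points until its count reaches
#' `balanceRatio` times the majority count. Each synthetic point is the class
#' centroid plus a Gaussian displacement whose per-feature SD is drawn
#' uniformly from `(0, sd0 * sdMaxFraction)` (`sd0` = per-feature SD of the
#' class), so synthetic density is highest near the centroid and expanded data
#' are not pushed toward the class margins. Original cells are never removed
#' or altered; already balanced input is returned unchanged.
#'
#' @param table a [FeatureTable-class].
#' @param grouping label column name (>= 2 classes; every augmented class
#'   needs >= 2 members).
#' @param config an [OversamplerConfig-class].
#' @return A [FeatureTable-class]; synthetic cells carry
#'   `cellData(x)$synthetic == TRUE` and `cell_id`s of the form
#'   `"<class>_synth_<i>"`.
#' @export
oversample <- function(table, grouping, config = oversamplerConfig()) {
  y <- groupLabels(table, grouping)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    .amStop("SingleClassError", "oversampling needs at least 2 classes")
  counts <- table(factor(y, classes))
  target <- ceiling(config@balanceRatio * max(counts))
  need <- pmax(0L, target - as.integer(counts))
  names(need) <- classes
  if (all(need == 0L)) return(table)
  x <- featureMatrix(table)
  cd <- as.data.frame(cellData(table))
  if (!"synthetic" %in% colnames(cd)) cd$synthetic <- FALSE
  newX <- list(); newCd <- list()
  .withSeed(config@seed, {
    for (cls in classes[need > 0L]) {
      xi <- x[y == cls, , drop = FALSE]
      if (nrow(xi) < 2L)
        .amStop("InsufficientSampleError",
                "class '%s' has < 2 members; cannot estimate its spread", cls)
      mu <- colMeans(xi)
      sd0 <- apply(xi, 2, sd)
      n <- need[[cls]]
      K <- ncol(xi)
      sds <- matrix(runif(n * K), n, K) * rep(sd0 * config@sdMaxFraction, each = n)
      pts <- rep(mu, each = n) + matrix(rnorm(n * K), n, K) * sds
      colnames(pts) <- colnames(xi)
      newX[[cls]] <- pts
      cdi <- cd[rep(which(y == cls)[1], n), , drop = FALSE]
      for (cc in setdiff(colnames(cdi), c(grouping, "synthetic"))) cdi[[cc]] <- NA
      if ("cell_id" %in% colnames(cdi))
        cdi$cell_id <- sprintf("%s_synth_%d", cls, seq_len(n))
      cdi$synthetic <- TRUE
      newCd[[cls]] <- cdi
    }
  })
  xa <- rbind(x, do.call(rbind, newX))
  rownames(xa) <- NULL
  cda <- rbind(cd, do.call(rbind, newCd))
  rownames(cda) <- NULL
  FeatureTable(xa, cda)
}

# -- one-vs-rest Random Forest ------------------------------------------------

.fitOvr <- function(x, y, seed, numTrees = 500, mtry = NULL) {
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    .amStop("SingleClassError", "training data covers a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  .withSeed(seed, {
    tieOrder <- sample(classes)
    models <- lapply(classes, function(cls)
      randomForest::randomForest(
        x = x, y = factor(ifelse(y == cls, "pos", "neg"), c("neg", "pos")),
        ntree = numTrees, mtry = min(mtry, ncol(x))))
    list(classes = classes, tieOrder = tieOrder, models = models)
  })
}

.predictOvr <- function(fit, x) {
  scores <- vapply(fit$models, function(m)
    predict(m, x, type = "prob")[, "pos"], numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  unname(apply(scores, 1, function(s) {
    cand <- fit$classes[s == max(s)]
    cand[which.min(match(cand, fit$tieOrder))]
  }))
}

#' Fit one-vs-rest Random Forests and predict test labels
#'
#' One bagged decision-tree ensemble (Random Forest) is trained per class
#' against the rest; a test cell is assigned the class whose binary model
#' yields the highest positive-class vote fraction, ties broken by a
#' seed-shuffled class order.
#'
#' @param train,test [FeatureTable-class]s with identical feature columns.
#' @param grouping label column name (train must cover >= 2 classes).
#' @param seed integer RNG seed (forest growth and tie order).
#' @param numTrees trees per binary forest (default 500).
#' @param mtry features tried per split (default `floor(sqrt(K))`).
#' @return Character vector of predicted labels, one per test cell.
#' @export
fitPredictOvr <- function(train, test, grouping, seed = 1L, numTrees = 500,
                          mtry = NULL) {
  xtr <- featureMatrix(train)
  xte <- featureMatrix(test)
  if (!identical(colnames(xtr), colnames(xte)))
    .amStop("SchemaError", "train and test feature columns differ")
  fit <- .fitOvr(xtr, groupLabels(train, grouping), seed, numTrees, mtry)
  .predictOvr(fit, xte)
}

#' Binary classification metrics from a confusion count quadruple
#'
#' Sensitivity (recall) `S = TP/(TP+FN)`, precision `P = TP/(TP+FP)`,
#' `F1 = 2PS/(P+S)` and accuracy `(TP+TN)/(TP+FP+TN+FN)`. Metrics whose
#' denominator is zero are reported as `NA` (undefined), never as 0.
#'
#' @param TP,FP,FN,TN nonnegative counts.
#' @return Named numeric vector `sensitivity`, `precision`, `f1`, `accuracy`.
#' @examples
#' binaryMetrics(TP = 2, FP = 1, FN = 1, TN = 6)
#' @export
binaryMetrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  S <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  F1 <- if (!is.na(S) && !is.na(P) && (P + S) > 0) 2 * P * S / (P + S)
        else NA_real_
  acc <- if (TP + FP + TN + FN > 0) (TP + TN) / (TP + FP + TN + FN)
         else NA_real_
  c(sensitivity = S, precision = P, f1 = F1, accuracy = acc)
}

.stratifiedSplit <- function(y, trainFraction, stratified, seed) {
  n <- length(y)
  .withSeed(seed, {
    if (stratified) {
      tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
        k <- round(trainFraction * length(ix))
        k <- max(1L, min(length(ix) - 1L, k))
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      k <- max(1L, min(n - 1L, round(trainFraction * n)))
      tr <- sample(n, k)
    }
    sort(tr)
  })
}

#' Repeated stratified train/test evaluation of the one-vs-rest classifier
#'
#' Per repeat: a stratified `trainFraction` split; minority oversampling of
#' the training portion only (the test fold is never touched, so there is no
#' leakage); one-vs-rest Random Forest fit; evaluation on the untouched test
#' fold. Reports per-repeat accuracies, per-class sensitivity/precision/F1
#' averaged over repeats, the pooled confusion matrix, and the accuracy of a
#' majority-vote baseline. Fully reproducible from the scheme and config seeds.
#'
#' @param table a [FeatureTable-class]; every class needs >= 4 members.
#' @param grouping label column name.
#' @param scheme a [SplitScheme-class].
#' @param config an [OversamplerConfig-class], or `NULL` to skip oversampling.
#' @param numTrees,mtry forest hyperparameters (see [fitPredictOvr()]).
#' @return A [ClassifierReport-class].
#' @export
repeatedEvaluate <- function(table, grouping, scheme = splitScheme(),
                             config = oversamplerConfig(), numTrees = 500,
                             mtry = NULL) {
  y <- groupLabels(table, grouping)
  classes <- sort(unique(y))
  counts <- table(factor(y, classes))
  if (any(counts < 4L))
    .amStop("InsufficientSampleError",
            "class(es) too small to stratify (< 4 cells): %s",
            paste(classes[counts < 4L], collapse = ", "))
  x <- featureMatrix(table)
  R <- scheme@repeats
  acc <- base <- numeric(R)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  mets <- array(NA_real_, c(R, length(classes), 3),
                dimnames = list(NULL, classes, c("sensitivity", "precision", "f1")))
  for (r in seq_len(R)) {
    sr <- .childSeed(scheme@seed, r)
    tr <- .stratifiedSplit(y, scheme@trainFraction, scheme@stratified, sr)
    trainTab <- table[, tr]
    if (!is.null(config)) {
      cfg <- initialize(config, seed = .childSeed(sr, 7L))
      trainTab <- oversample(trainTab, grouping, cfg)
    }
    fit <- .fitOvr(featureMatrix(trainTab), groupLabels(trainTab, grouping),
                   .childSeed(sr, 11L), numTrees, mtry)
    pred <- .predictOvr(fit, x[-tr, , drop = FALSE])
    truth <- y[-tr]
    acc[r] <- mean(pred == truth)
    base[r] <- mean(truth == names(which.max(table(y[tr]))))
    cm <- table(factor(truth, classes), factor(pred, classes))
    conf <- conf + cm
    for (ci in seq_along(classes)) {
      TP <- cm[ci, ci]; FP <- sum(cm[-ci, ci]); FN <- sum(cm[ci, -ci])
      TN <- sum(cm) - TP - FP - FN
      mets[r, ci, ] <- binaryMetrics(TP, FP, FN, TN)[c("sensitivity",
                                                       "precision", "f1")]
    }
  }
  cmDf <- data.frame(
    class = classes,
    sensitivity = colMeans(mets[, , "sensitivity", drop = FALSE], na.rm = TRUE),
    precision = colMeans(mets[, , "precision", drop = FALSE], na.rm = TRUE),
    f1 = colMeans(mets[, , "f1", drop = FALSE], na.rm = TRUE),
    support = as.integer(counts),
    row.names = NULL
  )
  new("ClassifierReport", accuracies = acc, baselineAccuracies = base,
      classMetrics = cmDf, confusion = unclass(conf), importance = numeric(),
      grouping = grouping)
}

#' @describeIn repeatedEvaluate per-repeat test accuracies.
#' @param report a [ClassifierReport-class].
#' @export
accuracies <- function(report) report@accuracies

#' @describeIn repeatedEvaluate mean accuracy over repeats.
#' @export
meanAccuracy <- function(report) mean(report@accuracies)

#' @describeIn repeatedEvaluate per-class metrics averaged over repeats.
#' @export
classMetrics <- function(report) report@classMetrics

#' @describeIn repeatedEvaluate pooled confusion matrix (truth x predicted).
#' @export
pooledConfusion <- function(report) report@confusion

#' @describeIn repeatedEvaluate per-repeat majority-vote baseline accuracies.
#' @export
baselineAccuracies <- function(report) report@baselineAccuracies

setMethod("show", "ClassifierReport", function(object) {
  a <- object@accuracies
  cat(sprintf("ClassifierReport ('%s', %d repeats)\n", object@grouping,
              length(a)))
  cat(sprintf("  accuracy: %.2f ± %.2f%% (majority baseline %.2f%%)\n",
              100 * mean(a), 100 * sd(a),
              100 * mean(object@baselineAccuracies)))
  print(transform(object@classMetrics,
                  sensitivity = round(sensitivity, 3),
                  precision = round(precision, 3), f1 = round(f1, 3)))
  if (length(object@importance)) {
    top <- head(sort(object@importance, decreasing = TRUE), 3)
    cat("  top MDA features:", paste(names(top), collapse = ", "), "\n")
  }
})

#' Mean-decrease-in-accuracy feature importance
#'
#' For each feature, the mean drop in test accuracy over repeated splits when
#' that feature's information is removed. Default mode neutralizes the feature
#' by permuting its column on the held-out test fold (the fitted ensemble is
#' reused); `mode = "retrain"` refits the ensemble without the feature
#' (exact removal, proportionally more expensive). Ranking is descending with
#' deterministic alphabetical tie-break.
#'
#' @inheritParams repeatedEvaluate
#' @param mode `"permutation"` (default) or `"retrain"`.
#' @return data.frame with columns `feature`, `importance`, `rank`, sorted by
#'   rank.
#' @export
mdaImportance <- function(table, grouping, scheme = splitScheme(),
                          config = oversamplerConfig(), mode = c("permutation",
                          "retrain"), numTrees = 500, mtry = NULL) {
  mode <- match.arg(mode)
  y <- groupLabels(table, grouping)
  x <- featureMatrix(table)
  K <- ncol(x)
  drops <- matrix(NA_real_, scheme@repeats, K, dimnames = list(NULL, colnames(x)))
  for (r in seq_len(scheme@repeats)) {
    sr <- .childSeed(scheme@seed, r)
    tr <- .stratifiedSplit(y, scheme@trainFraction, scheme@stratified, sr)
    trainTab <- table[, tr]
    if (!is.null(config))
      trainTab <- oversample(trainTab, grouping,
                             initialize(config, seed = .childSeed(sr, 7L)))
    xtr <- featureMatrix(trainTab); ytr <- groupLabels(trainTab, grouping)
    xte <- x[-tr, , drop = FALSE]; truth <- y[-tr]
    fit <- .fitOvr(xtr, ytr, .childSeed(sr, 11L), numTrees, mtry)
    acc0 <- mean(.predictOvr(fit, xte) == truth)
    for (k in seq_len(K)) {
      if (mode == "permutation") {
        xp <- xte
        xp[, k] <- .withSeed(.childSeed(sr, 100L + k),
                             xte[sample(nrow(xte)), k])
        accK <- mean(.predictOvr(fit, xp) == truth)
      } else {
        fitK <- .fitOvr(xtr[, -k, drop = FALSE], ytr, .childSeed(sr, 11L),
                        numTrees, mtry)
        accK <- mean(.predictOvr(fitK, xte[, -k, drop = FALSE]) == truth)
      }
      drops[r, k] <- acc0 - accK
    }
  }
  imp <- colMeans(drops)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp)[ord],
             rank = seq_len(K), row.names = NULL)
}
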