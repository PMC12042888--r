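makeImbalanced <- function(nA = 100, nB = 40, K = 3, seed = 1, sep = 0) {
  set.seed(seed)
  x <- matrix(rnorm((nA + nB) * K), nA + nB, K,
              dimnames = list(NULL, paste0("f", seq_len(K))))
  g <- rep(c("A", "B"), c(nA, nB))
  x[g == "B", 1] <- x[g == "B", 1] + sep
  FeatureTable(x, data.frame(cell_id = paste0("c", seq_len(nA + nB)),
                             group = g, stringsAsFactors = FALSE))
}

test_that("oversampling tops minority classes up to the balance ratio", {
  ft <- makeImbalanced(100, 40)
  out <- oversample(ft, "group", oversamplerConfig(balanceRatio = 0.9, seed = 3))
  counts <- table(groupLabels(out, "group"))
  expect_identical(unname(counts[["A"]]), 100L)
  expect_gte(counts[["B"]], 90L)
  # originals untouched, synthetic flagged
  expect_identical(featureMatrix(out)[1:140, ], featureMatrix(ft))
  expect_identical(sum(cellData(out)$synthetic), as.integer(counts[["B"]] - 40L))
  # balanced input returned unchanged
  bal <- makeImbalanced(50, 50)
  expect_identical(oversample(bal, "group"), bal)
  # reproducible from the seed
  out2 <- oversample(ft, "group", oversamplerConfig(balanceRatio = 0.9, seed = 3))
  expect_identical(featureMatrix(out), featureMatrix(out2))
  one <- makeImbalanced(10, 0)
  expect_error(oversample(one, "group"), class = "SingleClassError")
})

test_that("synthetic points concentrate near the minority centroid", {
  ft <- makeImbalanced(80, 20, K = 4, seed = 7)
  xB <- featureMatrix(ft)[groupLabels(ft, "group") == "B", ]
  mu <- colMeans(xB)
  dOrig <- mean(sqrt(rowSums(sweep(xB, 2, mu)^2)))
  dSynth <- vapply(1:50, function(s) {
    out <- oversample(ft, "group", oversamplerConfig(seed = s))
    xs <- featureMatrix(out)[cellData(out)$synthetic, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, mu)^2)))
  }, 1.0)
  expect_lte(mean(dSynth), dOrig)
})

test_that("one-vs-rest forests separate disjoint supports perfectly", {
  set.seed(5)
  x <- cbind(f1 = c(runif(40, 0, 1), runif(40, 3, 4)), f2 = rnorm(80))
  g <- rep(c("lo", "hi"), each = 40)
  ft <- FeatureTable(x, data.frame(group = g))
  train <- ft[, c(1:30, 41:70)]
  test <- ft[, c(31:40, 71:80)]
  pred <- fitPredictOvr(train, test, "group", seed = 2)
  expect_identical(pred, groupLabels(test, "group"))
  # a test point identical to a training point gets that point's class
  self <- fitPredictOvr(train, train[, 1], "group", seed = 2)
  expect_identical(self, "lo")
  bad <- FeatureTable(cbind(other = rnorm(5)), data.frame(group = rep("x", 5)))
  expect_error(fitPredictOvr(train, bad, "group"), class = "SchemaError")
})

test_that("binary metrics follow the S/P/F1/accuracy formulas", {
  m <- binaryMetrics(TP = 2, FP = 1, FN = 1, TN = 6)
  expect_equal(unname(m), c(2 / 3, 2 / 3, 2 / 3, 0.8))
  perfect <- binaryMetrics(TP = 5, FP = 0, FN = 0, TN = 10)
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  undef <- binaryMetrics(TP = 0, FP = 0, FN = 3, TN = 7)
  expect_identical(unname(undef[["precision"]]), NA_real_)
  expect_identical(unname(undef[["f1"]]), NA_real_)
  # F1 is a harmonic mean: between min and max of S and P
  set.seed(9)
  for (i in 1:50) {
    cnt <- sample(1:20, 4, replace = TRUE)
    m <- binaryMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(m[["f1"]] + 1e-12, min(m[["sensitivity"]], m[["precision"]]))
    expect_lte(m[["f1"]] - 1e-12, max(m[["sensitivity"]], m[["precision"]]))
  }
})

test_that("repeated evaluation reports per-repeat accuracies deterministically", {
  ft <- makeImbalanced(30, 24, seed = 3, sep = 8)   # cleanly separable
  sch <- splitScheme(repeats = 10L, seed = 5L)
  rep1 <- repeatedEvaluate(ft, "group", sch, numTrees = 100)
  expect_length(accuracies(rep1), 10L)
  expect_equal(meanAccuracy(rep1), 1)
  expect_equal(sd(accuracies(rep1)), 0)
  expect_equal(classMetrics(rep1)$f1, c(1, 1))
  # beats the majority baseline on separable data
  expect_gt(meanAccuracy(rep1), mean(baselineAccuracies(rep1)))
  # bit-identical under the same seeds
  rep2 <- repeatedEvaluate(ft, "group", sch, numTrees = 100)
  expect_identical(accuracies(rep1), accuracies(rep2))
  expect_identical(pooledConfusion(rep1), pooledConfusion(rep2))
  tiny <- makeImbalanced(10, 3)
  expect_error(repeatedEvaluate(tiny, "group"),
               class = "InsufficientSampleError")
})

test_that("oversampling never leaks into the test fold", {
  ft <- makeImbalanced(40, 16, seed = 8, sep = 2)
  sch <- splitScheme(repeats = 4L, seed = 2L)
  with <- repeatedEvaluate(ft, "group", sch, oversamplerConfig(), numTrees = 100)
  without <- repeatedEvaluate(ft, "group", sch, config = NULL, numTrees = 100)
  # same split seeds: identical test-fold composition in the pooled confusion
  expect_identical(rowSums(pooledConfusion(with)),
                   rowSums(pooledConfusion(without)))
  # test folds contain original cells only (counts match the raw class sizes)
  expect_identical(unname(rowSums(pooledConfusion(with))),
                   as.numeric(4 * c(40 - round(0.7 * 40), 16 - round(0.7 * 16))))
})

test_that("MDA importance finds planted signal and ignores constants", {
  set.seed(13)
  n <- 90
  g <- rep(c("A", "B", "C"), each = n / 3)
  x <- cbind(signal = as.numeric(factor(g)) + rnorm(n, 0, 0.15),
             noise1 = rnorm(n), noise2 = rnorm(n), flat = rep(1, n))
  ft <- FeatureTable(x, data.frame(group = g))
  imp <- mdaImportance(ft, "group", splitScheme(repeats = 5L, seed = 4L),
                       config = NULL, numTrees = 100)
  expect_identical(imp$feature[1], "signal")
  expect_lt(abs(imp$importance[imp$feature == "flat"]), 0.01)
  # deterministic, descending, alphabetical tie-break encoded in rank order
  imp2 <- mdaImportance(ft, "group", splitScheme(repeats = 5L, seed = 4L),
                        config = NULL, numTrees = 100)
  expect_identical(imp, imp2)
  expect_true(all(diff(imp$importance) <= 1e-12))
})
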