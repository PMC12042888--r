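test_that("min-max normalization maps to [0, 1] with pooled ranges", {
  ft <- FeatureTable(cbind(f1 = c(2, 4, 6), f2 = c(5, 5, 5)),
                     data.frame(group = c("A", "A", "B")))
  expect_warning(nt <- normalizeFeatures(ft), class = "ConstantFeatureWarning")
  expect_equal(unname(featureMatrix(nt)[, "f1"]), c(0, 0.5, 1))
  expect_equal(unname(featureMatrix(nt)[, "f2"]), c(0, 0, 0))
})

test_that("emd1d is the exact 1-Wasserstein distance", {
  expect_identical(emd1d(c(3, 1, 2), c(1, 3, 2)), 0)
  expect_equal(emd1d(c(0, 1), c(1, 2)), 1)
  a <- rnorm(20)
  expect_equal(emd1d(a, a + 0.7), 0.7, tolerance = 1e-12)
  expect_equal(emd1d(a, a - 1.3), 1.3, tolerance = 1e-12)
  expect_error(emd1d(numeric(), 1), class = "EmptySampleError")
  # unequal sizes against the sorted-transport oracle
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(emd1d(a, b), transportOracle(a, b), tolerance = 1e-9)
  }
})

test_that("signed EMD vectors carry translation distances and median signs", {
  ft <- randomFeatureTable(n = 40, K = 3, seed = 5)
  zero <- signedEmdVector(ft, "group", "A", "A", normalize = FALSE)
  expect_true(all(zero@d == 0))
  expect_true(all(zero@sign == 0L))

  x <- featureMatrix(ft)
  x2 <- x; x2[, 2] <- x2[, 2] + 0.2
  shifted <- FeatureTable(rbind(x, x2),
                          data.frame(group = rep(c("g1", "g2"), each = nrow(x))))
  ev <- signedEmdVector(shifted, "group", "g1", "g2", normalize = FALSE)
  expect_equal(unname(ev@d), c(0, 0.2, 0), tolerance = 1e-12)
  expect_identical(ev@sign, c(0L, 1L, 0L))
  rev <- signedEmdVector(shifted, "group", "g2", "g1", normalize = FALSE)
  expect_identical(rev@sign, -ev@sign)
  expect_equal(rev@d, ev@d)

  expect_error(signedEmdVector(ft, "group", "A", "nope"), class = "LabelError")
})

test_that("Spearman matrix is rank-based with average-rank ties", {
  set.seed(1)
  x <- runif(50, 0.1, 3)
  ft <- FeatureTable(cbind(a = x, cube = x^3, recip = 1 / x, noise = rnorm(50)),
                     data.frame(group = rep("A", 50)))
  R <- spearmanMatrix(ft)
  expect_equal(diag(R), setNames(rep(1, 4), colnames(R)))
  expect_equal(R["a", "cube"], 1)
  expect_equal(R["a", "recip"], -1)
  expect_true(isSymmetric(R))
  tiny <- FeatureTable(cbind(a = c(1, 2)), data.frame(group = c("A", "A")))
  expect_error(spearmanMatrix(tiny), class = "InsufficientSampleError")
})

test_that("morphological distance matches its closed forms and clamps", {
  expect_equal(as.numeric(morphologicalDistance(c(3, 4), diag(2))), 5)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  md <- morphologicalDistance(c(1, 1), R)
  expect_equal(as.numeric(md), sqrt(2.6), tolerance = 1e-12)  # 3.2 - 0.6
  expect_false(attr(md, "clamped"))
  Rneg <- matrix(c(1, -1, -1, 1), 2)
  expect_warning(mdc <- morphologicalDistance(c(1, 1), Rneg),
                 class = "NegativeMD2Warning")
  expect_identical(as.numeric(mdc), 0)
  expect_true(attr(mdc, "clamped"))
  expect_error(morphologicalDistance(c(1, 2, 3), diag(2)),
               class = "DimensionError")
})

test_that("with R = I the distance is the Euclidean norm of the EMD vector", {
  set.seed(7)
  for (i in 1:25) {
    d <- abs(rnorm(sample(2:15, 1)))
    expect_equal(as.numeric(morphologicalDistance(d, diag(length(d)))),
                 sqrt(sum(d^2)), tolerance = 1e-12)
  }
})

test_that("a feature with identical distributions contributes nothing", {
  set.seed(3)
  d <- abs(rnorm(5))
  R <- cor(matrix(rnorm(120), 20, 6), method = "spearman")
  md5 <- morphologicalDistance(d, R[1:5, 1:5])
  md6 <- morphologicalDistance(c(d, 0), R)
  expect_equal(as.numeric(md6), as.numeric(md5), tolerance = 1e-12)
})

test_that("the MD matrix is symmetric, zero-diagonal and detects duplicates", {
  ft <- randomFeatureTable(n = 60, K = 4, groups = c("A", "B", "C"), seed = 11,
                           shift = 1.5)
  x <- featureMatrix(ft)
  g <- groupLabels(ft, "group")
  # group D duplicates group A exactly
  dup <- FeatureTable(rbind(x, x[g == "A", ]),
                      data.frame(group = c(g, rep("D", sum(g == "A")))))
  m <- suppressWarnings(mdMatrix(dup, "group"))
  v <- mdValues(m)
  expect_identical(dim(v), c(4L, 4L))
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(0, 4))
  expect_true(all(v >= 0))
  expect_lt(v["A", "D"], 1e-12)
  expect_error(mdMatrix(randomFeatureTable(n = 10, groups = "A"), "group"),
               class = "InsufficientSampleError")
})

test_that("signed EMD tables have one column per comparison", {
  ft <- randomFeatureTable(n = 45, K = 3, groups = c("A", "B", "C"), seed = 2)
  tab <- signedEmdTable(ft, "group")
  expect_identical(colnames(tab), c("B vs A", "C vs A", "C vs B"))
  expect_identical(rownames(tab), paste0("f", 1:3))
})
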