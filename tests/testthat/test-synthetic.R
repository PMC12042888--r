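test_that("a soma without processes is close to the isoperimetric limit", {
  p <- silhouetteParams(nPrimary = 0L, somaRadius = c(20, 0), seed = 2)
  f <- computeFeatures(generateMask(p))
  expect_lt(abs(f[["sphericity"]] - 1), 0.05)
})

test_that("mask generation is deterministic per seed and yields valid masks", {
  p <- silhouetteParams(seed = 17)
  m1 <- generateMask(p)
  m2 <- generateMask(p)
  expect_identical(maskPixels(m1), maskPixels(m2))
  m3 <- generateMask(silhouetteParams(seed = 18))
  expect_false(identical(maskPixels(m1), maskPixels(m3)))
  # single 8-connected component and validity invariants
  for (seed in 1:8) {
    mk <- generateMask(silhouetteParams(imageSize = 128L, seed = seed))
    expect_true(validObject(mk))
    expect_identical(max(astromorph:::.label8(maskPixels(mk))), 1L)
  }
})

test_that("higher branching probability raises the median fractal dimension", {
  medFd <- vapply(c(0.05, 0.2, 0.5), function(bp) {
    fds <- vapply(1:25, function(i) {
      p <- silhouetteParams(imageSize = 192L, branchProb = bp,
                            seed = 1000 * round(100 * bp) + i)
      fractalDimension(generateMask(p))
    }, 1.0)
    median(fds)
  }, 1.0)
  expect_true(all(diff(medFd) > 0))
})

test_that("population generation attaches labels and supports mask retention", {
  spec <- populationSpec(nCells = 5, params = silhouetteParams(imageSize = 128L),
                         label = c(region = "AC"), seed = 3)
  ft <- generatePopulation(spec, keepMasks = TRUE)
  expect_s4_class(ft, "FeatureTable")
  expect_identical(ncol(ft), 5L)
  expect_identical(unique(groupLabels(ft, "region")), "AC")
  expect_length(attr(ft, "masks"), 5L)
  # deterministic
  ft2 <- generatePopulation(spec)
  expect_identical(featureMatrix(ft), featureMatrix(ft2))
})

test_that("copula sampling reproduces a prescribed Spearman correlation", {
  rho <- 0.7
  S <- matrix(c(1, rho, rho, 1), 2)
  spec <- populationSpec(nCells = 2000, marginals = uniformMarginals(2),
                         spearman = S, label = c(group = "g"), seed = 9)
  ft <- generatePopulation(spec)
  emp <- cor(featureMatrix(ft), method = "spearman")[1, 2]
  expect_lt(abs(emp - rho), 0.05)
  # independent draw when no target structure is given
  spec0 <- populationSpec(nCells = 2000, marginals = uniformMarginals(2),
                          label = c(group = "g"), seed = 9)
  emp0 <- cor(featureMatrix(generatePopulation(spec0)), method = "spearman")[1, 2]
  expect_lt(abs(emp0), 0.06)
})

test_that("well-separated silhouette populations are classified far above chance", {
  sepSpec <- function(mu, lab, seed) populationSpec(
    nCells = 40, params = silhouetteParams(imageSize = 192L,
                                           segmentLength = c(mu, 4)),
    label = c(group = lab), seed = seed)
  ft <- suppressWarnings(generatePopulations(list(
    sepSpec(14, "short", 201), sepSpec(26, "long", 202))))
  rep <- repeatedEvaluate(ft, "group", splitScheme(repeats = 5L, seed = 7L),
                          numTrees = 300)
  expect_gt(meanAccuracy(rep), mean(baselineAccuracies(rep)) + 0.25)
})

test_that("two identical specs are morphologically indistinguishable", {
  mk <- function(lab, seed) populationSpec(
    nCells = 400, marginals = uniformMarginals(4), label = c(group = lab),
    seed = seed)
  ft <- generatePopulations(list(mk("g1", 21), mk("g2", 22)))
  mdSame <- mdValues(suppressWarnings(mdMatrix(ft, "group")))["g1", "g2"]
  # resampling reference: split one exchangeable pool in half repeatedly
  x <- featureMatrix(ft)
  ref <- vapply(1:40, function(s) {
    set.seed(s)
    ix <- sample(nrow(x), nrow(x) / 2)
    ftr <- FeatureTable(x, data.frame(group = replace(rep("b", nrow(x)), ix, "a")))
    mdValues(suppressWarnings(mdMatrix(ftr, "group")))["a", "b"]
  }, 1.0)
  expect_lte(mdSame, quantile(ref, 0.95))
})
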