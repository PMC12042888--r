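test_that("preprocessMask restricts to a single 8-connected component", {
  blob <- matrix(FALSE, 20, 20)
  blob[3:12, 3:7] <- TRUE                       # 50 px
  expect_identical(maskPixels(preprocessMask(blob)), blob)

  two <- blob
  two[16:20, 16] <- TRUE                        # second blob, 5 px
  kept <- maskPixels(preprocessMask(two, keep = "largest"))
  expect_identical(kept, blob)
  expect_error(preprocessMask(two, keep = "strict"), class = "MultiComponentError")

  expect_error(preprocessMask(matrix(FALSE, 5, 5)), class = "EmptyMaskError")

  # diagonal adjacency is one component under 8-connectivity
  diag2 <- matrix(FALSE, 8, 8); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_silent(preprocessMask(diag2, keep = "strict"))
})

test_that("the feature vector has the 15 named descriptors and internal identities", {
  f <- suppressWarnings(computeFeatures(rasterDisk(20)))
  expect_identical(names(f), morphometricFeatureNames())
  expect_length(f, 15L)
  expect_equal(unname(f["sphericity"] * f["spherical_disproportion"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(f["perimeter_to_surface_ratio"]),
               unname(f["perimeter"] / f["area"]), tolerance = 1e-9)
  expect_equal(unname(f["equivalent_diameter_area"]),
               sqrt(4 * unname(f["area"]) / pi), tolerance = 1e-12)
  expect_equal(unname(f["elongation"]),
               unname(f["minor_axis_length"] / f["major_axis_length"]),
               tolerance = 1e-12)
})

test_that("a digitized disk is near the isoperimetric/symmetry limit", {
  f <- suppressWarnings(computeFeatures(rasterDisk(20)))
  expect_lt(abs(f[["sphericity"]] - 1), 0.05)
  expect_lt(f[["eccentricity"]], 0.1)
  expect_gt(f[["solidity"]], 0.95)
  expect_lte(f[["solidity"]], 1)
  expect_gte(f[["lacunarity"]], 1)
})

test_that("max Feret diameter follows the pixel-center convention", {
  m <- matrix(FALSE, 3, 7); m[2, 2:6] <- TRUE    # 1x5 line
  f <- suppressWarnings(computeFeatures(m))
  expect_identical(unname(f["max_feret_diameter"]), 4)
  # brute force over all foreground pixel pairs
  idx <- which(m, arr.ind = TRUE)
  expect_equal(unname(f["max_feret_diameter"]), max(dist(idx)))
})

test_that("hole filling is the only filled quantity", {
  d <- rasterDisk(20)
  inner <- which(d & ((row(d) - 24)^2 + (col(d) - 24)^2 <= 16))[1:30]
  d2 <- d; d2[inner] <- FALSE                    # punched 30-px interior hole
  f <- suppressWarnings(computeFeatures(d2))
  expect_identical(unname(f["area_filled"] - f["area"]), 30)
})

test_that("degenerate single-pixel masks are rejected", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_error(computeFeatures(m), class = "DegenerateMaskError")
})

test_that("box-counting dimension matches plane, line and Sierpinski limits", {
  expect_equal(fractalDimension(matrix(TRUE, 256, 256)), 2, tolerance = 0.1)
  expect_equal(fractalDimension(rasterLine(256)), 1, tolerance = 0.1)
  expect_equal(fractalDimension(sierpinskiRaster(6)), log(3) / log(2),
               tolerance = 0.08)
  expect_error(fractalDimension(diag(4) > 0), class = "InsufficientScalesError")
})

test_that("box counts agree with a brute-force window counter on Sierpinski", {
  m <- sierpinskiRaster(5)
  for (s in c(1L, 2L, 4L, 8L)) {
    expect_identical(astromorph:::.boxCount(m, s), bruteBoxCount(m, s))
  }
})

test_that("gliding-box lacunarity has its analytic values and lower bound", {
  expect_equal(lacunarity(matrix(TRUE, 32, 32)), 1, tolerance = 1e-12)
  expect_equal(lacunarity(checkerboard8()), 2, tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) < 0.4, 32, 32)
    m[1, 1] <- m[32, 32] <- TRUE                 # pin the bounding box
    expect_gte(lacunarity(m), 1)
  }
  expect_error(lacunarity(matrix(rep(c(TRUE, FALSE), 10), 4, 5)),
               class = "InsufficientScalesError")
})

test_that("90/180-degree rotations leave every feature unchanged exactly", {
  for (seed in c(3, 11)) {
    mk <- generateMask(silhouetteParams(seed = seed))
    px <- maskPixels(mk)
    f0 <- computeFeatures(px)
    expect_identical(computeFeatures(rot90cw(px)), f0)
    expect_identical(computeFeatures(rot90cw(rot90cw(px))), f0)
  }
})

test_that("upscaling scales area exactly and lengths within 5%", {
  # pixel replication: area is exactly s^2-fold, calipers scale with s
  mk <- generateMask(silhouetteParams(imageSize = 128L, seed = 9))
  px <- maskPixels(mk)
  f1 <- computeFeatures(px)
  s <- 2L
  f2 <- computeFeatures(upscaleMask(px, s))
  expect_identical(unname(f2["area"]), unname(f1["area"]) * s^2)
  expect_equal(unname(f2["max_feret_diameter"]),
               unname(f1["max_feret_diameter"]) * s, tolerance = 0.05)
  expect_equal(unname(f2["solidity"]), unname(f1["solidity"]), tolerance = 0.05)
  expect_equal(unname(f2["elongation"]), unname(f1["elongation"]),
               tolerance = 0.05)
  # boundary-dependent features scale with resolution: digitize the same
  # continuous shape (a disk) on grids s apart (pixel replication preserves
  # staircase jaggedness, which a boundary-step estimator rightly measures)
  d1 <- suppressWarnings(computeFeatures(rasterDisk(16)))
  d2 <- suppressWarnings(computeFeatures(rasterDisk(32)))
  expect_equal(unname(d2["perimeter"] / d1["perimeter"]), 2, tolerance = 0.05)
  expect_equal(unname(d2["area"] / d1["area"]), 4, tolerance = 0.05)
  expect_equal(unname(d2["sphericity"]), unname(d1["sphericity"]),
               tolerance = 0.05)
})

test_that("feature extraction is bit-identical across runs and respects pixelSize", {
  mk <- generateMask(silhouetteParams(seed = 21))
  expect_identical(computeFeatures(mk), computeFeatures(mk))
  mk2 <- CellMask(maskPixels(mk), pixelSize = 0.5)
  fpx <- computeFeatures(mk2)
  fum <- computeFeatures(mk2, applyPixelSize = TRUE)
  expect_equal(unname(fum["area"]), unname(fpx["area"]) * 0.25)
  expect_equal(unname(fum["perimeter"]), unname(fpx["perimeter"]) * 0.5)
  expect_identical(unname(fum["sphericity"]), unname(fpx["sphericity"]))
  expect_identical(unname(fum["fractal_dimension"]),
                   unname(fpx["fractal_dimension"]))
})
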