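# -- low-level raster helpers -------------------------------------------------

.shiftMat <- function(px, dr, dc) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  out[rs + dr, cs + dc] <- px[rs, cs]
  out
}

.cropBBox <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  px[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

# clockwise 90-degree rotation
.rot90 <- function(m) t(m[nrow(m):1L, , drop = FALSE])

.asMaskMatrix <- function(mask) {
  if (is(mask, "CellMask")) mask@pixels
  else {
    storage.mode(mask) <- "logical"
    mask
  }
}

# -- perimeter ----------------------------------------------------------------

# Weighted boundary-step perimeter (Benkrid-Crookes configuration weights, the
# estimator scikit-image uses): border pixels are foreground pixels removed by
# 4-connected erosion; each contributes a weight determined by how many of its
# straight (S) and diagonal (D) neighbors are border pixels, code = 1+2S+10D.
.perimeterWeighted <- function(px) {
  eroded <- px &
    .shiftMat(px, 1L, 0L) & .shiftMat(px, -1L, 0L) &
    .shiftMat(px, 0L, 1L) & .shiftMat(px, 0L, -1L)
  border <- px & !eroded
  if (!any(border)) return(0)
  S <- .shiftMat(border, 1L, 0L) + .shiftMat(border, -1L, 0L) +
       .shiftMat(border, 0L, 1L) + .shiftMat(border, 0L, -1L)
  D <- .shiftMat(border, 1L, 1L) + .shiftMat(border, 1L, -1L) +
       .shiftMat(border, -1L, 1L) + .shiftMat(border, -1L, -1L)
  code <- 1L + 2L * S + 10L * D
  w <- numeric(49L)
  w[c(5L, 7L, 15L, 17L, 25L, 27L)] <- 1
  w[c(21L, 33L)] <- sqrt(2)
  w[c(13L, 23L)] <- (1 + sqrt(2)) / 2
  sum(w[code[border]])
}

# -- moment ellipse -----------------------------------------------------------

# Second-central-moment ellipse of the foreground pixel centers: axis lengths
# 4*sqrt(eigenvalue) of the coordinate covariance, as in standard regionprops.
# Central moments come from integer power sums on bounding-box coordinates, so
# they are exact and bit-identical under translation and 90-degree rotation.
.momentEllipse <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  if (nrow(idx) < 2L)
    .amStop("DegenerateMaskError",
            "moment ellipse undefined for a %d-pixel mask", nrow(idx))
  y <- as.numeric(idx[, 1] - min(idx[, 1]))
  x <- as.numeric(idx[, 2] - min(idx[, 2]))
  n <- nrow(idx)
  num20 <- n * sum(x^2) - sum(x)^2
  num02 <- n * sum(y^2) - sum(y)^2
  num11 <- n * sum(x * y) - sum(x) * sum(y)
  mu20 <- num20 / n^2
  mu02 <- num02 / n^2
  mu11 <- num11 / n^2
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  if (l1 <= 0)
    .amStop("DegenerateMaskError", "moment ellipse undefined (zero extent)")
  list(eccentricity = sqrt(1 - l2 / l1),
       major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

# -- Feret diameter and convex hull -------------------------------------------

# Maximum pairwise distance between foreground pixel centers (attained on the
# convex hull, so only hull vertices are compared).
.feretMax <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[hull, , drop = FALSE]
  max(dist(pts))
}

# Pixelized convex hull area: number of pixel centers inside or on the convex
# hull polygon of the foreground centers. Guarantees hull area >= area, so
# solidity stays in (0, 1].
.hullPixelArea <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  if (length(unique(hull)) < 3L) return(nrow(idx))  # collinear foreground
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  rr <- min(idx[, 1]):max(idx[, 1])
  cc <- min(idx[, 2]):max(idx[, 2])
  gx <- rep(cc, each = length(rr))
  gy <- rep(rr, times = length(cc))
  sum(pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE))
}

# -- fractal dimension --------------------------------------------------------

.boxCount <- function(m, s) {
  idx <- which(m, arr.ind = TRUE)
  bc <- (idx[, 2] - 1L) %/% s
  br <- (idx[, 1] - 1L) %/% s
  length(unique(br * (((ncol(m) - 1L) %/% s) + 1L) + bc))
}

.dyadicScales <- function(h, w) {
  smax <- max(h, w) / 2
  s <- 1L
  out <- integer()
  while (s <= smax) {
    out <- c(out, s)
    s <- s * 2L
  }
  # drop the largest scale if fewer than 4 boxes tile the bounding box
  while (length(out) &&
         ceiling(h / out[length(out)]) * ceiling(w / out[length(out)]) < 4L)
    out <- out[-length(out)]
  out
}

#' Box-counting fractal dimension of a silhouette
#'
#' Counts occupied boxes `N(s)` over dyadic box sizes on the foreground
#' bounding box and returns the negative least-squares slope of
#' `log N(s)` vs `log s`. To remove grid-placement bias (and make the value
#' exactly invariant to 90/180-degree rotations) `N(s)` is the minimal cover
#' over the four corner anchorings of the grid.
#'
#' @param mask a [CellMask-class] or logical matrix with at least 16
#'   foreground pixels.
#' @return The estimated dimension, typically in `[1, 2]` for connected
#'   silhouettes.
#' @examples
#' sq <- matrix(TRUE, 64, 64)
#' fractalDimension(sq)  # plane-filling: 2
#' @export
fractalDimension <- function(mask) {
  px <- .asMaskMatrix(mask)
  if (sum(px) < 16L)
    .amStop("InsufficientScalesError",
            "fractal dimension needs >= 16 foreground pixels (got %d)", sum(px))
  m <- .cropBBox(px)
  scales <- .dyadicScales(nrow(m), ncol(m))
  if (length(scales) < 3L)
    .amStop("InsufficientScalesError",
            "only %d usable box scales; at least 3 required", length(scales))
  rots <- list(m, .rot90(m), .rot90(.rot90(m)), .rot90(.rot90(.rot90(m))))
  counts <- vapply(scales, function(s)
    min(vapply(rots, .boxCount, 1L, s = s)), 1L)
  fit <- stats::lm.fit(cbind(1, log(scales)), log(counts))
  -unname(fit$coefficients[2])
}

# -- lacunarity ---------------------------------------------------------------

#' Gliding-box lacunarity of a silhouette
#'
#' For each dyadic box size `r` in `{2, 4, ..., min(h, w)/4}` of the foreground
#' bounding box, box masses `M` are collected over the non-overlapping `r x r`
#' tiling (partial edge boxes discarded) and
#' `Lambda(r) = mean(M^2) / mean(M)^2`; the statistic is averaged over the four
#' corner anchorings of the grid (exact 90-degree rotation invariance) and then
#' over scales. `Lambda = 1` for a translation-invariant mass distribution and
#' grows with gappiness; by Jensen's inequality `Lambda >= 1` always.
#'
#' @inheritParams fractalDimension
#' @return Mean lacunarity over the dyadic scales (>= 1).
#' @examples
#' lacunarity(matrix(TRUE, 32, 32))  # homogeneous: 1
#' @export
lacunarity <- function(mask) {
  px <- .asMaskMatrix(mask)
  if (sum(px) < 16L)
    .amStop("InsufficientScalesError",
            "lacunarity needs >= 16 foreground pixels (got %d)", sum(px))
  m <- .cropBBox(px)
  rmax <- min(nrow(m), ncol(m)) / 4
  rs <- integer()
  r <- 2L
  while (r <= rmax) {
    rs <- c(rs, r)
    r <- r * 2L
  }
  if (!length(rs))
    .amStop("InsufficientScalesError",
            "bounding box %d x %d too small for any gliding-box scale",
            nrow(m), ncol(m))
  rots <- list(m, .rot90(m), .rot90(.rot90(m)), .rot90(.rot90(.rot90(m))))
  lamAtScale <- function(r) {
    mean(vapply(rots, function(mm) {
      nbr <- nrow(mm) %/% r; nbc <- ncol(mm) %/% r
      idx <- which(mm, arr.ind = TRUE)
      ok <- idx[, 1] <= nbr * r & idx[, 2] <= nbc * r
      idx <- idx[ok, , drop = FALSE]
      ids <- ((idx[, 1] - 1L) %/% r) * nbc + ((idx[, 2] - 1L) %/% r) + 1L
      M <- tabulate(ids, nbins = nbr * nbc)
      mean(M^2) / mean(M)^2
    }, 1.0))
  }
  mean(vapply(rs, lamAtScale, 1.0))
}

# -- the 15-feature vector ----------------------------------------------------

#' Names of the 15 morphometric descriptors
#'
#' @return Character vector of the feature names, in canonical order.
#' @export
morphometricFeatureNames <- function() {
  c("area", "area_filled", "equivalent_diameter_area", "max_feret_diameter",
    "eccentricity", "perimeter", "perimeter_to_surface_ratio", "sphericity",
    "spherical_disproportion", "solidity", "major_axis_length",
    "minor_axis_length", "elongation", "fractal_dimension", "lacunarity")
}

#' Compute the 15 morphometric features of one cell
#'
#' Definitions (lengths in pixels unless `applyPixelSize`):
#' * `area` — foreground pixel count; `area_filled` — count after hole filling.
#' * `equivalent_diameter_area` — diameter of the equal-area circle,
#'   `sqrt(4 * area / pi)`.
#' * `max_feret_diameter` — maximum caliper: largest pairwise distance between
#'   foreground pixel centers.
#' * `eccentricity`, `major_axis_length`, `minor_axis_length`, `elongation`
#'   (= minor/major) — from the second-central-moment ellipse.
#' * `perimeter` — weighted boundary-step estimator (see
#'   [fractalDimension()] for the companion complexity measures);
#'   `perimeter_to_surface_ratio` = perimeter / area.
#' * `sphericity` — 2-D circularity `2 * sqrt(pi * area) / perimeter`;
#'   `spherical_disproportion` — its reciprocal.
#' * `solidity` — area / pixelized convex-hull area.
#' * `fractal_dimension`, `lacunarity` — see [fractalDimension()] and
#'   [lacunarity()]; on masks too small for 3 box scales these are `NA` with a
#'   warning.
#'
#' Holes are retained everywhere except `area_filled`.
#'
#' @param mask a [CellMask-class] (or logical matrix, taken as a mask with
#'   pixel size 1).
#' @param applyPixelSize if `TRUE`, scale length features by the mask's
#'   `pixelSize` and area features by its square; dimensionless features are
#'   never scaled.
#' @return Named numeric vector of length 15 (order of
#'   [morphometricFeatureNames()]).
#' @examples
#' p <- silhouetteParams(seed = 7)
#' computeFeatures(generateMask(p))
#' @export
computeFeatures <- function(mask, applyPixelSize = FALSE) {
  if (!is(mask, "CellMask")) mask <- CellMask(.asMaskMatrix(mask))
  px <- mask@pixels
  area <- sum(px)
  if (area < 2L)
    .amStop("DegenerateMaskError", "mask with %d pixel(s) is degenerate", area)
  filled <- EBImage::fillHull(matrix(as.integer(px), nrow(px))) > 0
  perim <- .perimeterWeighted(px)
  ell <- .momentEllipse(px)
  sph <- 2 * sqrt(pi * area) / perim
  fd <- tryCatch(fractalDimension(px), astromorphError = function(e) {
    .amWarn("FeatureWarning", "fractal_dimension set to NA: %s", conditionMessage(e))
    NA_real_
  })
  lac <- tryCatch(lacunarity(px), astromorphError = function(e) {
    .amWarn("FeatureWarning", "lacunarity set to NA: %s", conditionMessage(e))
    NA_real_
  })
  v <- c(
    area = area,
    area_filled = sum(filled),
    equivalent_diameter_area = sqrt(4 * area / pi),
    max_feret_diameter = .feretMax(px),
    eccentricity = ell$eccentricity,
    perimeter = perim,
    perimeter_to_surface_ratio = perim / area,
    sphericity = sph,
    spherical_disproportion = 1 / sph,
    solidity = area / .hullPixelArea(px),
    major_axis_length = ell$major,
    minor_axis_length = ell$minor,
    elongation = ell$minor / ell$major,
    fractal_dimension = fd,
    lacunarity = lac
  )
  if (applyPixelSize) {
    ps <- mask@pixelSize
    lenF <- c("equivalent_diameter_area", "max_feret_diameter", "perimeter",
              "major_axis_length", "minor_axis_length")
    v[c("area", "area_filled")] <- v[c("area", "area_filled")] * ps^2
    v[lenF] <- v[lenF] * ps
    v["perimeter_to_surface_ratio"] <- v["perimeter"] / v["area"]
  }
  v[morphometricFeatureNames()]
}
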