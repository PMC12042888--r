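#' Silhouette generator parameters
#'
#' @param imageSize side of the square raster (pixels).
#' @param somaRadius `c(mean, sd)` of the soma radius (pixels).
#' @param nPrimary number of primary processes.
#' @param branchProb bifurcation probability per segment.
#' @param segmentLength `c(mean, sd)` of segment length (pixels).
#' @param tortuosity SD of the angular jitter per segment (radians).
#' @param thickness process width at the soma (pixels; tapered with depth).
#' @param seed integer RNG seed.
#' @return A [SilhouetteParams-class].
#' @export
silhouetteParams <- function(imageSize = 256L, somaRadius = c(12, 2),
                             nPrimary = 6L, branchProb = 0.15,
                             segmentLength = c(18, 6), tortuosity = 0.3,
                             thickness = 3, seed = 1L) {
  new("SilhouetteParams", imageSize = as.integer(imageSize),
      somaRadius = as.numeric(somaRadius), nPrimary = as.integer(nPrimary),
      branchProb = as.numeric(branchProb),
      segmentLength = as.numeric(segmentLength),
      tortuosity = as.numeric(tortuosity), thickness = as.numeric(thickness),
      seed = as.integer(seed))
}

# Stamp a disk of radius rad at every (row, col) center into the raster.
.stampDisks <- function(px, rows, cols, rad) {
  h <- nrow(px); w <- ncol(px)
  r <- max(0L, as.integer(ceiling(rad)))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  rr <- rep(round(rows), each = nrow(off)) + off$dr
  cc <- rep(round(cols), each = nrow(off)) + off$dc
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  px[cbind(rr[ok], cc[ok])] <- TRUE
  px
}

#' Generate one branched astrocyte-like silhouette
#'
#' Draws a central disk soma and grows `nPrimary` primary processes as chains
#' of thick segments: each segment's direction is jittered by the tortuosity,
#' and at each segment end the process bifurcates with probability
#' `branchProb` (spawning two tapered children) or continues. The recursion is
#' a stochastic L-system standing in for GFAP-labeled arborization; the result
#' is a single 8-connected component by construction and is deterministic per
#' seed.
#'
#' @param params a [SilhouetteParams-class].
#' @param cellId,imageId,labels metadata attached to the returned mask.
#' @return A [CellMask-class].
#' @examples
#' generateMask(silhouetteParams(seed = 42))
#' @export
generateMask <- function(params, cellId = "synthetic", imageId = "synthetic",
                         labels = character()) {
  sz <- params@imageSize
  px <- matrix(FALSE, sz, sz)
  ctr <- (sz + 1) / 2
  maxDepth <- 6L
  contProb <- 0.8
  px <- .withSeed(params@seed, {
    somaR <- max(2, rnorm(1, params@somaRadius[1], params@somaRadius[2]))
    somaR <- min(somaR, sz / 4)
    px <- .stampDisks(px, ctr, ctr, somaR)
    # stack of growth tips: x, y, angle, depth
    tips <- lapply(seq_len(params@nPrimary), function(p)
      list(x = ctr, y = ctr,
           ang = 2 * pi * (p - 1) / max(1L, params@nPrimary) + rnorm(1, 0, 0.2),
           depth = 0L))
    # advance each tip off the soma rim before drawing
    tips <- lapply(tips, function(tp) {
      tp$x <- tp$x + (somaR - 1) * cos(tp$ang)
      tp$y <- tp$y + (somaR - 1) * sin(tp$ang)
      tp
    })
    while (length(tips)) {
      tp <- tips[[length(tips)]]
      tips[[length(tips)]] <- NULL
      L <- max(3, rnorm(1, params@segmentLength[1], params@segmentLength[2]))
      ang <- tp$ang + rnorm(1, 0, params@tortuosity)
      th <- max(1, params@thickness * 0.85^tp$depth)
      nStep <- max(2L, ceiling(2 * L))
      t <- seq(0, L, length.out = nStep)
      xs <- tp$x + t * cos(ang)
      ys <- tp$y + t * sin(ang)
      inb <- xs >= 2 & xs <= sz - 1 & ys >= 2 & ys <= sz - 1
      if (!all(inb)) {           # clip at the border and stop this process
        keep <- which(!inb)[1] - 1L
        if (keep < 2L) next
        xs <- xs[seq_len(keep)]; ys <- ys[seq_len(keep)]
        px <- .stampDisks(px, ys, xs, th / 2)
        next
      }
      px <- .stampDisks(px, ys, xs, th / 2)
      if (tp$depth < maxDepth) {
        if (runif(1) < params@branchProb) {
          spread <- 0.4 + runif(1, 0, 0.5)
          for (s in c(-1, 1))
            tips[[length(tips) + 1L]] <- list(
              x = xs[length(xs)], y = ys[length(ys)],
              ang = ang + s * spread, depth = tp$depth + 1L)
        } else if (runif(1) < contProb) {
          tips[[length(tips) + 1L]] <- list(
            x = xs[length(xs)], y = ys[length(ys)], ang = ang,
            depth = tp$depth + 1L)
        }
      }
    }
    px
  })
  if (!any(px))
    .amStop("GenerationError", "parameters produced an empty mask")
  CellMask(px, cellId = cellId, imageId = imageId, labels = labels)
}

#' Specify a synthetic cell population
#'
#' @param nCells number of cells (>= 2).
#' @param params a [SilhouetteParams-class] (mask mode).
#' @param label named character vector of annotations for every cell, e.g.
#'   `c(region = "AC")`.
#' @param marginals feature-distribution mode: named list of quantile
#'   functions, one per feature (overrides mask mode).
#' @param spearman optional target Spearman matrix coupling the marginals via
#'   a Gaussian copula.
#' @param seed integer RNG seed.
#' @return A [PopulationSpec-class].
#' @export
populationSpec <- function(nCells, params = silhouetteParams(),
                           label = character(), marginals = list(),
                           spearman = NULL, seed = 1L) {
  new("PopulationSpec", label = label, nCells = as.integer(nCells),
      params = params, marginals = marginals, spearman = spearman,
      seed = as.integer(seed))
}

# Gaussian copula sample with target Spearman matrix: for bivariate normals,
# spearman = (6/pi) asin(pearson/2), inverted per entry.
.copulaSample <- function(n, marginals, spearman, seed) {
  K <- length(marginals)
  .withSeed(seed, {
    Z <- matrix(rnorm(n * K), n, K)
    if (!is.null(spearman)) {
      P <- 2 * sin(pi * spearman / 6)
      diag(P) <- 1
      ev <- eigen(P, symmetric = TRUE)
      if (min(ev$values) < 1e-10)
        .amStop("GenerationError", "target Spearman matrix is not positive definite")
      Z <- Z %*% t(ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
    }
    U <- pnorm(Z)
    X <- vapply(seq_len(K), function(k) marginals[[k]](U[, k]), numeric(n))
    colnames(X) <- names(marginals)
    X
  })
}

#' Generate a synthetic cell population as a FeatureTable
#'
#' Mask mode (default): `nCells` silhouettes are generated (each with a child
#' seed derived from the spec seed), preprocessed, and pushed through
#' [computeFeatures()]. Feature-distribution mode (when the spec carries
#' marginals): feature vectors are drawn directly from the prescribed
#' marginals coupled by a Gaussian copula, bypassing rasterization so the
#' distance and classification modules can be tested against exactly known
#' distributions.
#'
#' @param spec a [PopulationSpec-class].
#' @param keepMasks in mask mode, also return the generated [CellMask-class]
#'   list as attribute `"masks"`.
#' @return A [FeatureTable-class] with the spec labels in `cellData`.
#' @export
generatePopulation <- function(spec, keepMasks = FALSE) {
  lab <- spec@label
  if (length(spec@marginals)) {
    X <- .copulaSample(spec@nCells, spec@marginals, spec@spearman, spec@seed)
    cd <- data.frame(cell_id = sprintf("cell_%03d", seq_len(spec@nCells)),
                     stringsAsFactors = FALSE)
    for (ln in names(lab)) cd[[ln]] <- unname(lab[[ln]])
    return(FeatureTable(X, cd))
  }
  masks <- lapply(seq_len(spec@nCells), function(i) {
    p <- initialize(spec@params, seed = .childSeed(spec@seed, i))
    m <- generateMask(p, cellId = sprintf("cell_%03d", i),
                      imageId = sprintf("sim_%s", paste(lab, collapse = "_")),
                      labels = lab)
    preprocessMask(m)
  })
  ft <- computeFeatureTable(masks)
  if (keepMasks) attr(ft, "masks") <- masks
  ft
}

#' @describeIn generatePopulation generate and combine several populations.
#' @param specs list of [PopulationSpec-class] objects.
#' @export
generatePopulations <- function(specs) {
  combineFeatureTables(lapply(specs, generatePopulation))
}
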