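#' Construct a CellMask
#'
#' @param pixels logical (or coercible 0/1) matrix, `TRUE`/nonzero = foreground.
#' @param pixelSize physical pixel size (micrometres per pixel).
#' @param cellId,imageId identifier strings.
#' @param labels named character vector of categorical annotations.
#' @return A [CellMask-class] object.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' CellMask(m, cellId = "c1")
#' @export
CellMask <- function(pixels, pixelSize = 1, cellId = "cell", imageId = "image",
                     labels = character()) {
  if (!is.matrix(pixels)) .amStop("EmptyMaskError", "'pixels' must be a matrix")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  new("CellMask", pixels = pixels, pixelSize = as.numeric(pixelSize),
      cellId = as.character(cellId), imageId = as.character(imageId),
      labels = labels)
}

#' @describeIn CellMask foreground raster as a logical matrix.
#' @param object,x a `CellMask`.
#' @export
maskPixels <- function(x) x@pixels

#' @describeIn CellMask physical pixel size.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn CellMask cell identifier.
#' @export
cellId <- function(x) x@cellId

#' @describeIn CellMask categorical annotations.
#' @export
cellLabels <- function(x) x@labels

setMethod("show", "CellMask", function(object) {
  px <- object@pixels
  cat(sprintf("CellMask '%s' (image '%s'): %d x %d raster, %d foreground px, pixelSize %g\n",
              object@cellId, object@imageId, nrow(px), ncol(px), sum(px),
              object@pixelSize))
  if (length(object@labels))
    cat("  labels:", paste(names(object@labels), object@labels, sep = "=",
                           collapse = ", "), "\n")
})

# 8-connected component labeling by vectorized BFS. Returns an integer matrix,
# 0 = background, components numbered in row-major order of their first pixel.
.label8 <- function(px) {
  h <- nrow(px); w <- ncol(px)
  lab <- matrix(0L, h, w)
  todo <- which(px)
  if (!length(todo)) return(lab)
  nextLab <- 0L
  remaining <- px
  # neighbor offsets in linear (column-major) indexing, guarded by row wrap
  for (seedIdx in seq_along(todo)) {
    start <- todo[seedIdx]
    if (!remaining[start]) next
    nextLab <- nextLab + 1L
    frontier <- start
    remaining[start] <- FALSE
    lab[start] <- nextLab
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      nb <- c(
        frontier[r > 1L] - 1L, frontier[r < h] + 1L,
        frontier[cc > 1L] - h, frontier[cc < w] + h,
        frontier[r > 1L & cc > 1L] - h - 1L, frontier[r < h & cc > 1L] - h + 1L,
        frontier[r > 1L & cc < w] + h - 1L, frontier[r < h & cc < w] + h + 1L
      )
      nb <- unique(nb[remaining[nb]])
      if (length(nb)) {
        remaining[nb] <- FALSE
        lab[nb] <- nextLab
      }
      frontier <- nb
    }
  }
  lab
}

#' Preprocess a raw segmentation raster into a valid CellMask
#'
#' Restricts the foreground to a single 8-connected component, the invariant
#' every downstream feature assumes. Under `keep = "largest"` (default) the
#' largest component is retained (ties broken by first pixel in row-major
#' order); under `keep = "strict"` multiple components are an error.
#'
#' @param raw logical/0-1 matrix or a [CellMask-class].
#' @param keep `"largest"` or `"strict"`.
#' @param ... passed to [CellMask()] (pixelSize, cellId, imageId, labels).
#' @return A [CellMask-class] whose foreground is one 8-connected component.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[2:8, 2:8] <- TRUE; m[11, 11] <- TRUE
#' sum(maskPixels(preprocessMask(m)))  # small blob dropped
#' @export
preprocessMask <- function(raw, keep = c("largest", "strict"), ...) {
  keep <- match.arg(keep)
  if (is(raw, "CellMask")) {
    px <- raw@pixels
    mk <- function(p) initialize(raw, pixels = p)
  } else {
    if (!is.matrix(raw)) .amStop("EmptyMaskError", "'raw' must be a matrix")
    px <- raw
    storage.mode(px) <- "logical"
    px[is.na(px)] <- FALSE
    mk <- function(p) CellMask(p, ...)
  }
  if (!any(px)) .amStop("EmptyMaskError", "raster contains no foreground pixels")
  lab <- .label8(px)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (keep == "strict")
      .amStop("MultiComponentError",
              "foreground has %d 8-connected components under policy 'strict'", ncomp)
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    px <- lab == which.max(sizes)
  }
  mk(px)
}
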