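#' Read a label image (TIFF or PNG)
#'
#' Label rasters use 0 for background and one positive integer per cell.
#' 8/16-bit TIFFs are read with their integer values; PNGs are assumed 8-bit
#' (values rescaled from [0, 1] by 255).
#'
#' @param path image file path (`.tif`, `.tiff` or `.png`).
#' @return Integer matrix of labels.
#' @export
readLabelImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      .amStop("ParseError", "the 'png' package is required to read %s", path)
    img <- round(png::readPNG(path) * 255)
  } else {
    .amStop("ParseError", "unsupported image extension '%s'", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background).
#' @param path output `.tif` path.
#' @return The path, invisibly.
#' @export
writeLabelImage <- function(labels, path) {
  if (max(labels) > 65535L)
    .amStop("ParseError", "more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Split a label raster into per-cell masks
#'
#' @param labels integer matrix (0 = background; each positive value = one
#'   cell) as returned by [readLabelImage()].
#' @param imageId identifier stored on each mask.
#' @param pixelSize physical pixel size.
#' @param metadata optional data.frame with a `cell_id` column and label
#'   columns (`region`, `treatment`, ...); matched by `"<imageId>_<label>"`
#'   or the bare label value.
#' @return List of [CellMask-class] objects (each preprocessed to its largest
#'   8-connected component).
#' @export
masksFromLabels <- function(labels, imageId = "image", pixelSize = 1,
                            metadata = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids)) .amStop("EmptyMaskError", "label raster contains no cells")
  lapply(ids, function(id) {
    cid <- sprintf("%s_%d", imageId, id)
    labs <- character()
    if (!is.null(metadata)) {
      row <- metadata[metadata$cell_id %in% c(cid, as.character(id)), , drop = FALSE]
      if (nrow(row) == 1L) {
        keep <- setdiff(colnames(row), c("cell_id", "image_id"))
        labs <- setNames(as.character(unlist(row[1, keep])), keep)
        labs <- labs[!is.na(labs)]
      }
    }
    preprocessMask(labels == id, keep = "largest", pixelSize = pixelSize,
                   cellId = cid, imageId = imageId, labels = labs)
  })
}

# -- VGG Image Annotator (VIA) JSON -------------------------------------------

#' Read rectangular bounding boxes from a VIA project JSON
#'
#' Parses the VGG Image Annotator project format (either the full project
#' with `_via_img_metadata` or a bare image-metadata map) into one record per
#' rectangular region. Coordinates are 0-based, half-open pixel coordinates
#' (x, y = top-left corner; the box covers `[x, x+width) x [y, y+height)`).
#' Non-rectangular regions are skipped with a warning.
#'
#' @param path JSON file path.
#' @return data.frame with columns `image_id`, `x`, `y`, `width`, `height`.
#' @export
readViaAnnotations <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) .amStop("ParseError",
                    "malformed VIA JSON in %s: %s", path, conditionMessage(e)))
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]]
          else doc
  out <- list()
  nSkipped <- 0L
  for (entry in meta) {
    if (!is.list(entry) || is.null(entry$filename)) next
    for (reg in entry$regions) {
      sa <- reg$shape_attributes
      if (is.null(sa$name) || sa$name != "rect") {
        nSkipped <- nSkipped + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        image_id = entry$filename, x = as.numeric(sa$x), y = as.numeric(sa$y),
        width = as.numeric(sa$width), height = as.numeric(sa$height),
        stringsAsFactors = FALSE)
    }
  }
  if (nSkipped)
    .amWarn("NonRectRegionWarning", "skipped %d non-rectangular region(s)",
            nSkipped)
  if (!length(out))
    return(data.frame(image_id = character(), x = numeric(), y = numeric(),
                      width = numeric(), height = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write bounding boxes as a VIA project JSON
#'
#' Inverse of [readViaAnnotations()]: writes a minimal VIA project whose
#' rectangular regions round-trip exactly.
#'
#' @param boxes data.frame with columns `image_id`, `x`, `y`, `width`,
#'   `height`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeViaAnnotations <- function(boxes, path) {
  need <- c("image_id", "x", "y", "width", "height")
  if (!all(need %in% colnames(boxes)))
    .amStop("SchemaError", "boxes must have columns: %s",
            paste(need, collapse = ", "))
  meta <- lapply(split(boxes, boxes$image_id), function(b) {
    list(filename = b$image_id[1], size = -1L,
         regions = lapply(seq_len(nrow(b)), function(i)
           list(shape_attributes = list(name = "rect", x = b$x[i], y = b$y[i],
                                        width = b$width[i], height = b$height[i]),
                region_attributes = setNames(list(), character()))),
         file_attributes = setNames(list(), character()))
  })
  jsonlite::write_json(list(`_via_img_metadata` = meta), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
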