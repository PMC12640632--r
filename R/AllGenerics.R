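#' Extract the pixel matrix
#'
#' @param x a \linkS4class{PressureImage} or \linkS4class{BinaryMask}.
#' @return integer matrix indexed \code{[row, col]} (\code{[y+1, x+1]}).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Image width in pixels
#' @param x an image-like object.
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))

#' Image height in pixels
#' @param x an image-like object.
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))

#' kPa per intensity unit
#' @param x a \linkS4class{PressureImage}.
#' @export
setGeneric("pressureScale", function(x) standardGeneric("pressureScale"))

#' List of traced contours
#' @param x a \linkS4class{ContourSet}.
#' @return list of n x 2 integer matrices with columns x, y (0-based).
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))

#' Shoelace areas of a contour set
#' @param x a \linkS4class{ContourSet}.
#' @export
setGeneric("contourAreas", function(x) standardGeneric("contourAreas"))

#' Region boxes of a partition or report
#' @param x a \linkS4class{FootPartition}.
#' @return data.frame with columns label, x, y, w, h.
#' @export
setGeneric("partitionBoxes", function(x) standardGeneric("partitionBoxes"))

#' @rdname pixels
#' @export
setMethod("pixels", "PressureImage", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname imgWidth
#' @export
setMethod("imgWidth", "PressureImage", function(x) ncol(x@pixels))
#' @rdname imgWidth
#' @export
setMethod("imgWidth", "BinaryMask", function(x) ncol(x@pixels))

#' @rdname imgHeight
#' @export
setMethod("imgHeight", "PressureImage", function(x) nrow(x@pixels))
#' @rdname imgHeight
#' @export
setMethod("imgHeight", "BinaryMask", function(x) nrow(x@pixels))

#' @rdname pressureScale
#' @export
setMethod("pressureScale", "PressureImage", function(x) x@pressureScale)

#' @rdname contours
#' @export
setMethod("contours", "ContourSet", function(x) x@contours)

#' @rdname contourAreas
#' @export
setMethod("contourAreas", "ContourSet", function(x) x@areas)

#' Number of contours
#' @param x a \linkS4class{ContourSet}.
#' @export
setMethod("length", "ContourSet", function(x) length(x@contours))

#' @rdname partitionBoxes
#' @export
setMethod("partitionBoxes", "FootPartition", function(x) x@regions)

setMethod("show", "PressureImage", function(object) {
  cat(sprintf("PressureImage %dx%d px, intensities [%d, %d], %.3g kPa/unit\n",
    imgWidth(object), imgHeight(object),
    min(object@pixels), max(object@pixels), object@pressureScale))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %dx%d px, %d foreground px (%.1f%%)\n",
    imgWidth(object), imgHeight(object), sum(object@pixels > 0),
    100 * mean(object@pixels > 0)))
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet with %d contour(s)\n", length(object@contours)))
  if (length(object@contours)) {
    a <- object@areas
    cat(sprintf("  shoelace areas: min %.0f, median %.0f, max %.0f px^2\n",
      min(a), stats::median(a), max(a)))
  }
})

setMethod("show", "FootPartition", function(object) {
  cat(sprintf("FootPartition (%s foot): length %d px, bands fore/arch/heel = %d/%d/%d\n",
    object@side, object@footLength, object@bands["fore"],
    object@bands["arch"], object@bands["heel"]))
  print(object@regions, row.names = FALSE)
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(
    "SynthSpec: %s / %s, %dx%d px, foot length %d, contact %.2f, %s, noise sd %.1f\n",
    object@footType, object@side, object@imageSize[1], object@imageSize[2],
    object@footLength, object@midfootContact, object@completeness,
    object@noiseSd))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (two-step normal/abnormal aggregation)\n")
  print(object@perRegion, row.names = FALSE, digits = 3)
  cat(sprintf("mean IoU %.3f | mAP %.3f | AP protocol: IoU in {%s}\n",
    object@meanIoU, object@mapScore,
    paste(format(object@protocol$iouThresholds), collapse = ", ")))
  if (nrow(object@failures))
    cat(sprintf("%d failed image/side cell(s)\n", nrow(object@failures)))
})
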