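#' @import methods
NULL

#' Pressure image container
#'
#' An 8-bit plantar pressure image. Pixels are stored as an integer matrix
#' indexed \code{[row, col]}; the repo-wide coordinate convention is origin at
#' the top-left, \code{x} rightward (column) and \code{y} downward (row), with
#' all exported point and rectangle coordinates 0-based. Intensities are raw
#' sensor units in \code{[0, 255]}; \code{pressureScale} converts one
#' intensity unit to kPa (the reference scanner maps intensity 1:1 to kPa, so
#' the default is 1).
#'
#' @slot pixels integer matrix of intensities in \code{[0, 255]}.
#' @slot pressureScale kPa per intensity unit.
#' @export
setClass("PressureImage",
  representation(pixels = "matrix", pressureScale = "numeric"),
  prototype(pixels = matrix(0L, 1, 1), pressureScale = 1)
)

setValidity("PressureImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1 || ncol(p) < 1) return("image must be at least 1x1")
  if (anyNA(p)) return("pixels must not contain NA")
  if (any(p < 0 | p > 255)) return("intensities must lie in [0, 255]")
  if (any(p != round(p))) return("intensities must be integral")
  if (length(object@pressureScale) != 1 || object@pressureScale <= 0)
    return("pressureScale must be a single positive number")
  TRUE
})

#' Binary segmentation mask
#'
#' Output of every segmentation backend: a matrix of the same shape as the
#' source image holding strictly binary values 0 (background) and 255
#' (foreground / edge).
#'
#' @slot pixels integer matrix with values in \{0, 255\}.
#' @export
setClass("BinaryMask", representation(pixels = "matrix"),
  prototype(pixels = matrix(0L, 1, 1))
)

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (anyNA(p)) return("pixels must not contain NA")
  if (!all(p %in% c(0, 255))) return("mask values must be strictly 0 or 255")
  TRUE
})

#' Set of traced contours
#'
#' Ordered closed boundaries traced from a binary mask. Each contour is an
#' integer matrix with columns \code{x}, \code{y} (0-based pixel centres);
#' consecutive points are 8-adjacent and the first/last points wrap
#' implicitly. \code{areas} holds the matching shoelace areas in squared
#' pixels.
#'
#' @slot contours list of n x 2 integer matrices.
#' @slot areas numeric vector, one shoelace area per contour.
#' @export
setClass("ContourSet",
  representation(contours = "list", areas = "numeric"),
  prototype(contours = list(), areas = numeric(0))
)

setValidity("ContourSet", function(object) {
  if (length(object@contours) != length(object@areas))
    return("areas must match contours in length")
  if (any(object@areas < 0)) return("areas must be non-negative")
  ok <- vapply(object@contours, function(m) is.matrix(m) && ncol(m) == 2,
    logical(1))
  if (!all(ok)) return("every contour must be an n x 2 matrix")
  TRUE
})

#' Proportional partition of one foot
#'
#' The four anatomical region boxes of a single foot, derived from the
#' toe-excluded contour point set: foot length is split top-down into
#' forefoot / arch / heel bands of 30/30/40 percent, and the forefoot band is
#' split vertically at its x-midpoint into outer and inner halves (mirrored
#' between left and right feet). Rectangles use half-open pixel semantics
#' \code{[x, x+w) x [y, y+h)}.
#'
#' @slot side "left" or "right".
#' @slot footLength inclusive pixel count along y.
#' @slot bands named integer vector (fore, arch, heel) summing to footLength.
#' @slot yRange named integer vector (ymin, ymax), inclusive.
#' @slot xExtents named integer vector of the per-band x extremes
#'   (foreMin, foreMax, archMin, archMax, heelMin, heelMax).
#' @slot regions data.frame with columns label, x, y, w, h (one row per
#'   region: outerForefoot, innerForefoot, midfoot, heel).
#' @export
setClass("FootPartition",
  representation(side = "character", footLength = "integer",
    bands = "integer", yRange = "integer", xExtents = "integer",
    regions = "data.frame")
)

setValidity("FootPartition", function(object) {
  if (!object@side %in% c("left", "right")) return("side must be left/right")
  if (sum(object@bands) != object@footLength)
    return("bands must sum to footLength")
  if (!identical(sort(names(object@bands)), sort(c("fore", "arch", "heel"))))
    return("bands must be named fore/arch/heel")
  if (nrow(object@regions) != 4) return("exactly four region boxes expected")
  if (!identical(sort(object@regions$label), sort(regionLabels())))
    return("region labels must be the fixed 4-label vocabulary")
  if (any(object@regions$w < 1) || any(object@regions$h < 1))
    return("region boxes must have positive extent")
  TRUE
})

#' Segmentation evaluation report
#'
#' Scores of predicted partitions against ground-truth boxes: per
#' side-by-region mean IoU and average precision with the two-step
#' (normal/abnormal group means first, then their unweighted mean)
#' aggregation, pooled means for transparency, qualitative performance bands,
#' and the summary mAP.
#'
#' @slot perRegion data.frame, one row per side x region cell.
#' @slot meanIoU unweighted mean of the per-cell two-step IoU means.
#' @slot mapScore mean of the per-cell average precisions.
#' @slot groupMeans data.frame of per-group and overall means.
#' @slot failures data.frame of image/side cells with no usable prediction.
#' @slot protocol list describing the AP protocol (IoU threshold grid).
#' @export
setClass("EvalReport",
  representation(perRegion = "data.frame", meanIoU = "numeric",
    mapScore = "numeric", groupMeans = "data.frame",
    failures = "data.frame", protocol = "list")
)

#' Specification for one synthetic pressure image
#'
#' Parameters of the synthetic plantar pressure generator. One image holds a
#' left and/or right footprint of one of the five morphologies; ground truth
#' is computed from the noise-free geometry.
#'
#' @slot footType one of normal, low_arch, high_arch, inward_tilt,
#'   outward_tilt.
#' @slot side "left", "right" or "both" (default: both feet in one image).
#' @slot imageSize integer (width, height) in pixels.
#' @slot footLength sole length (toes excluded) in pixels.
#' @slot midfootContact fraction of midfoot width in contact, in [0, 1].
#' @slot completeness complete, missing_toes or incomplete.
#' @slot noiseSd sensor-grid noise standard deviation (intensity units).
#' @slot seed integer seed (NA for unseeded).
#' @export
setClass("SynthSpec",
  representation(footType = "character", side = "character",
    imageSize = "integer", footLength = "integer",
    midfootContact = "numeric", completeness = "character",
    noiseSd = "numeric", seed = "integer")
)

setValidity("SynthSpec", function(object) {
  if (!object@footType %in% footTypes()) return("unknown footType")
  if (!object@side %in% c("left", "right", "both")) return("bad side")
  if (!object@completeness %in% c("complete", "missing_toes", "incomplete"))
    return("bad completeness")
  if (object@midfootContact < 0 || object@midfootContact > 1)
    return("midfootContact must lie in [0, 1]")
  if (any(object@imageSize < 32)) return("imageSize too small")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  # the foot (sole + toe margin) must fit inside its half/full canvas
  halfW <- if (object@side == "both") object@imageSize[1] %/% 2 else
    object@imageSize[1]
  L <- object@footLength
  if (1.25 * L > object@imageSize[2] || 0.45 * L > halfW)
    return("foot does not fit inside the image with margin")
  TRUE
})
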