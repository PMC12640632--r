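#' The fixed anatomical region vocabulary
#'
#' Region labels in canonical order: lateral forefoot half, medial forefoot
#' half, midfoot (arch) band, heel band.
#' @return character vector of length 4.
#' @export
regionLabels <- function() {
  c("outerForefoot", "innerForefoot", "midfoot", "heel")
}

#' The five synthetic foot morphologies
#' @return character vector of length 5.
#' @export
footTypes <- function() {
  c("normal", "low_arch", "high_arch", "inward_tilt", "outward_tilt")
}

#' Construct a pixel rectangle
#'
#' Rectangles are half-open pixel sets \code{[x, x+w) x [y, y+h)} with
#' 0-based top-left corner, so \code{w * h} is an exact pixel count and
#' \code{bottomRight = (x+w, y+h)}.
#'
#' @param x,y top-left corner (0-based pixels).
#' @param w,h extents in pixels, at least 1.
#' @return named numeric vector \code{c(x, y, w, h)}.
#' @export
pixelRect <- function(x, y, w, h) {
  stopifnot(w >= 1, h >= 1)
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

#' Construct a PressureImage
#'
#' @param pixels numeric/integer matrix of intensities in \code{[0, 255]},
#'   indexed \code{[row, col]}.
#' @param pressureScale kPa per intensity unit (default 1).
#' @return a \linkS4class{PressureImage}.
#' @export
PressureImage <- function(pixels, pressureScale = 1) {
  storage.mode(pixels) <- "integer"
  new("PressureImage", pixels = pixels, pressureScale = pressureScale)
}

#' Construct a BinaryMask
#' @param pixels matrix with values 0/255 (or logical, mapped to 0/255).
#' @return a \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels * 255L
  storage.mode(pixels) <- "integer"
  new("BinaryMask", pixels = pixels)
}

# shared guard for the segmentation backends
.assertImage <- function(img) {
  if (!methods::is(img, "PressureImage"))
    stop("expected a PressureImage", call. = FALSE)
  invisible(img)
}

# smoothstep ramp: 0 below e0, 1 above e1, C1-smooth between
.smoothstep <- function(t, e0, e1) {
  u <- pmin(pmax((t - e0) / (e1 - e0), 0), 1)
  u * u * (3 - 2 * u)
}
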