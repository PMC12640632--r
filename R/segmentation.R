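#' Simple (global) thresholding
#'
#' Classical binary thresholding: \code{dst = maxVal} where
#' \code{src > thresh} (strict inequality), else 0. The reference pipeline
#' uses \code{thresh = 127}.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param thresh global threshold in \code{[0, 255]}.
#' @param maxVal value written to foreground pixels (255).
#' @return a \linkS4class{BinaryMask}.
#' @export
thresholdSimple <- function(img, thresh = 127, maxVal = 255) {
  .assertImage(img)
  stopifnot(thresh >= 0, thresh <= 255)
  BinaryMask((pixels(img) > thresh) * as.integer(maxVal))
}

#' Otsu's thresholding
#'
#' Selects the threshold maximizing the between-class variance of the 256-bin
#' intensity histogram (equivalently, exhaustive search over all 256
#' candidate cuts; ties resolved toward the smallest threshold), then
#' binarizes with the same strict \code{src > thresh} rule as
#' \code{\link{thresholdSimple}}.
#'
#' @param img a \linkS4class{PressureImage} with at least two distinct
#'   intensities.
#' @return list with elements \code{threshold} (integer) and \code{mask}
#'   (a \linkS4class{BinaryMask}).
#' @export
thresholdOtsu <- function(img) {
  .assertImage(img)
  p <- pixels(img)
  h <- tabulate(as.vector(p) + 1L, nbins = 256)
  if (sum(h > 0) < 2)
    stop("degenerate input: constant image has no Otsu threshold",
      call. = FALSE)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h) / n                 # class 0: intensity <= t
  mu0 <- cumsum(h * lev) / pmax(cumsum(h), 1)
  muT <- sum(h * lev) / n
  w1 <- 1 - w0
  mu1 <- (muT - w0 * mu0) / ifelse(w1 > 0, w1, NA)
  sigmaB <- w0 * w1 * (mu0 - mu1)^2
  sigmaB[w0 == 0 | w1 == 0] <- -Inf   # both classes must be non-empty
  t <- lev[which.max(sigmaB)]         # first maximum = smallest threshold
  list(threshold = t, mask = thresholdSimple(img, thresh = t))
}

#' Adaptive (local mean) thresholding
#'
#' Per-pixel threshold equal to the mean of the surrounding
#' \code{blockSize x blockSize} window minus \code{C}; a pixel is foreground
#' when strictly above its local threshold. Borders are handled by reflect
#' padding.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param blockSize odd window side, at least 3, not larger than the image.
#' @param C offset subtracted from the local mean (intensity units).
#' @return a \linkS4class{BinaryMask}.
#' @export
thresholdAdaptive <- function(img, blockSize = 11, C = 2) {
  .assertImage(img)
  if (blockSize %% 2 != 1 || blockSize < 3)
    stop("blockSize must be odd and >= 3", call. = FALSE)
  if (blockSize > min(imgWidth(img), imgHeight(img)))
    stop("blockSize larger than the image", call. = FALSE)
  p <- pixels(img)
  thr <- .boxMean(p, blockSize) - C
  BinaryMask((p > thr) * 255L)
}

#' Named parameter presets of the reference pipeline
#'
#' The published defaults: simple threshold 127; split-and-merge boundary
#' window (50, 100); Canny double thresholds (100, 200), (200, 300) and
#' (300, 600), the last capturing only the outer foot contour and used by
#' the hybrid pipeline.
#'
#' @return nested list of parameter sets.
#' @export
segmentationPresets <- function() {
  list(
    threshold = list(default = list(thresh = 127, maxVal = 255)),
    splitmerge = list(default = list(minThresh = 50, maxThresh = 100,
      minRegion = 4, tol = 16)),
    canny = list(
      fine = list(minVal = 100, maxVal = 200),
      medium = list(minVal = 200, maxVal = 300),
      outer = list(minVal = 300, maxVal = 600)
    )
  )
}

#' Dispatch a segmentation backend by name
#'
#' @param img a \linkS4class{PressureImage}.
#' @param method "threshold", "splitmerge" or "canny".
#' @param params named list overriding the method's preset defaults.
#' @return a \linkS4class{BinaryMask}.
#' @export
segmentImage <- function(img, method = c("canny", "threshold", "splitmerge"),
                         params = list()) {
  method <- match.arg(method)
  presets <- segmentationPresets()
  p <- switch(method,
    threshold = utils::modifyList(presets$threshold$default, params),
    splitmerge = utils::modifyList(presets$splitmerge$default, params),
    canny = utils::modifyList(presets$canny$outer, params)
  )
  switch(method,
    threshold = thresholdSimple(img, thresh = p$thresh, maxVal = p$maxVal),
    splitmerge = splitMerge(img, minRegion = p$minRegion, tol = p$tol,
      minThresh = p$minThresh, maxThresh = p$maxThresh),
    canny = canny(img, minVal = p$minVal, maxVal = p$maxVal)
  )
}
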