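#' Canny edge detection (five-stage cascade)
#'
#' From-scratch implementation of the classical cascade:
#' \enumerate{
#'   \item Gaussian smoothing (separable, reflect padding);
#'   \item intensity gradient by 3x3 Sobel operators, L2 magnitude without
#'     normalization (so magnitudes of an ideal full-height step reach well
#'     above 255, which is what makes the published (300, 600) double
#'     threshold meaningful);
#'   \item non-maximum suppression with the gradient direction quantized to
#'     four bins (0, 45, 90, 135 degrees), nearest-neighbour comparison,
#'     ties kept;
#'   \item double thresholding into strong (magnitude >= maxVal), weak
#'     (>= minVal) and non-edge pixels;
#'   \item edge tracking by hysteresis: weak pixels survive only with an
#'     8-connected path to a strong pixel.
#' }
#'
#' @param img a \linkS4class{PressureImage}.
#' @param minVal,maxVal double thresholds in gradient-magnitude units,
#'   \code{minVal < maxVal}. Published presets: (100, 200), (200, 300) and
#'   (300, 600); the last keeps only the outer foot contour.
#' @param ksize odd Gaussian kernel side (default 5).
#' @param sigma Gaussian standard deviation in pixels (default 0.8, so the
#'   5-tap kernel covers about three standard deviations each side).
#' @return a \linkS4class{BinaryMask} of edge pixels.
#' @export
canny <- function(img, minVal = 300, maxVal = 600, ksize = 5, sigma = 0.8) {
  .assertImage(img)
  if (minVal >= maxVal) stop("minVal must be < maxVal", call. = FALSE)
  if (ksize %% 2 != 1) stop("ksize must be odd", call. = FALSE)
  g <- .cannyGradient(pixels(img), ksize, sigma)
  nms <- .cannyNms(g$mag, g$gx, g$gy)
  strong <- (nms & g$mag >= maxVal) * 1L
  weak <- (nms & g$mag >= minVal & g$mag < maxVal) * 1L
  storage.mode(strong) <- "integer"
  storage.mode(weak) <- "integer"
  BinaryMask(cpp_hysteresis(strong, weak))
}

# stages 1-2: blur + Sobel gradient
.cannyGradient <- function(p, ksize, sigma) {
  sm <- .gaussianBlur(p, ksize, sigma)
  # 3x3 Sobel, separable: d/dx = smooth [1 2 1] along y, diff [-1 0 1] along x
  gx <- .convRows(.convCols(sm, c(-1, 0, 1)), c(1, 2, 1))
  gy <- .convCols(.convRows(sm, c(-1, 0, 1)), c(1, 2, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# stage 3: non-maximum suppression, direction quantized to 4 bins
.cannyNms <- function(mag, gx, gy) {
  theta <- atan2(gy, gx) * 180 / pi
  theta <- theta %% 180
  bin <- integer(length(theta))
  bin[theta >= 22.5 & theta < 67.5] <- 1L   # gradient along (+1, +1)
  bin[theta >= 67.5 & theta < 112.5] <- 2L  # along (0, +-1)
  bin[theta >= 112.5 & theta < 157.5] <- 3L # along (+1, -1)
  dim(bin) <- dim(mag)
  n1 <- mag; n2 <- mag
  sel <- bin == 0L
  s1 <- .shiftMat(mag, 1, 0); s2 <- .shiftMat(mag, -1, 0)
  n1[sel] <- s1[sel]; n2[sel] <- s2[sel]
  sel <- bin == 1L
  s1 <- .shiftMat(mag, 1, 1); s2 <- .shiftMat(mag, -1, -1)
  n1[sel] <- s1[sel]; n2[sel] <- s2[sel]
  sel <- bin == 2L
  s1 <- .shiftMat(mag, 0, 1); s2 <- .shiftMat(mag, 0, -1)
  n1[sel] <- s1[sel]; n2[sel] <- s2[sel]
  sel <- bin == 3L
  s1 <- .shiftMat(mag, 1, -1); s2 <- .shiftMat(mag, -1, 1)
  n1[sel] <- s1[sel]; n2[sel] <- s2[sel]
  mag >= n1 & mag >= n2 & mag > 0
}

#' Gradient field of the Canny cascade
#'
#' Exposes the smoothed-gradient magnitude used internally, for tests and
#' parameter studies.
#'
#' @inheritParams canny
#' @return list with matrices \code{gx}, \code{gy}, \code{mag}.
#' @export
cannyGradient <- function(img, ksize = 5, sigma = 0.8) {
  .assertImage(img)
  .cannyGradient(pixels(img), ksize, sigma)
}
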