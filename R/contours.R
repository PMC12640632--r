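#' Trace outer border contours of a binary mask
#'
#' Border following in the Suzuki-Abe tradition: every 8-connected
#' foreground component contributes the ordered, closed sequence of its
#' outer border pixels (clockwise in screen coordinates, starting from the
#' topmost-then-leftmost pixel). Inner borders (holes) are ignored.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return a \linkS4class{ContourSet}; empty for an empty mask.
#' @export
traceContours <- function(mask) {
  if (!methods::is(mask, "BinaryMask")) stop("expected a BinaryMask")
  cs <- cpp_trace_contours(pixels(mask))
  new("ContourSet", contours = cs,
    areas = vapply(cs, shoelaceArea, numeric(1)))
}

#' Shoelace (surveyor's) polygon area
#'
#' Absolute value of the signed shoelace sum halved,
#' \eqn{\frac{1}{2} |\sum_j (x_j y_{j+1} - x_{j+1} y_j)|}, over the closed
#' point sequence (last point wraps to the first). Orientation-independent.
#' Contour points are pixel centres at integer coordinates, so the result
#' slightly underestimates the filled pixel count of a blob (by at most
#' about half the perimeter).
#'
#' @param points n x 2 matrix of (x, y) vertices.
#' @return area in squared pixels; 0 when fewer than 3 points.
#' @export
shoelaceArea <- function(points) {
  n <- nrow(points)
  if (is.null(n) || n < 3) return(0)
  x <- as.numeric(points[, 1]); y <- as.numeric(points[, 2])
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Filter contours by minimum shoelace area
#'
#' Keeps exactly the contours whose area is strictly greater than
#' \code{minArea} (the reference pipeline uses 6000 squared pixels, which in
#' practice removes toe blobs while keeping the sole). Order is preserved.
#'
#' @param cs a \linkS4class{ContourSet}.
#' @param minArea strict lower bound in squared pixels.
#' @return the filtered \linkS4class{ContourSet}.
#' @export
filterByArea <- function(cs, minArea = 6000) {
  keep <- cs@areas > minArea
  new("ContourSet", contours = cs@contours[keep], areas = cs@areas[keep])
}

#' Bounding boxes and left/right foot assignment
#'
#' Computes the minimal axis-aligned bounding rectangle of each contour
#' (half-open, so \code{w = max(x) - min(x) + 1}) and assigns it to the left
#' foot when the box's top-left \code{x < imgWidth / 2}, else to the right
#' foot. A contour whose box straddles the midline is assigned left by this
#' literal rule and flagged in the \code{ambiguous} column.
#'
#' @param cs a filtered \linkS4class{ContourSet}.
#' @param imgWidth full image width in pixels.
#' @return data.frame with one row per contour: side, x, y, w, h, contour
#'   (index into \code{cs}), ambiguous.
#' @export
assignRegions <- function(cs, imgWidth) {
  n <- length(cs@contours)
  if (n == 0)
    return(data.frame(side = character(0), x = numeric(0), y = numeric(0),
      w = numeric(0), h = numeric(0), contour = integer(0),
      ambiguous = logical(0), stringsAsFactors = FALSE))
  boxes <- t(vapply(cs@contours, function(m) {
    c(min(m[, 1]), min(m[, 2]), max(m[, 1]) - min(m[, 1]) + 1,
      max(m[, 2]) - min(m[, 2]) + 1)
  }, numeric(4)))
  side <- ifelse(boxes[, 1] < imgWidth / 2, "left", "right")
  ambiguous <- boxes[, 1] < imgWidth / 2 &
    boxes[, 1] + boxes[, 3] > imgWidth / 2
  if (any(ambiguous))
    message(sum(ambiguous), " contour(s) straddle the midline; assigned left")
  data.frame(side = side, x = boxes[, 1], y = boxes[, 2], w = boxes[, 3],
    h = boxes[, 4], contour = seq_len(n), ambiguous = ambiguous,
    stringsAsFactors = FALSE)
}
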