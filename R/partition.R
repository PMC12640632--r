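#' Collect the toe-excluded point set of one foot
#'
#' Union of the contour points of every filtered contour assigned to the
#' requested side. Toe exclusion is realized upstream by the shoelace-area
#' filter: toe blobs fall below the minimum area and never enter the
#' filtered set, while a high-arch foot whose forefoot and heel are
#' disconnected contributes both large contours.
#'
#' @param cs the filtered \linkS4class{ContourSet}.
#' @param regions data.frame from \code{\link{assignRegions}} on \code{cs}.
#' @param side "left" or "right".
#' @return integer matrix of unique (x, y) points.
#' @export
collectFootPoints <- function(cs, regions, side = c("left", "right")) {
  side <- match.arg(side)
  idx <- regions$contour[regions$side == side]
  if (!length(idx))
    stop("missing foot: no filtered contour on the ", side, " side",
      call. = FALSE)
  pts <- do.call(rbind, cs@contours[idx])
  unique(pts)
}

#' Foot length along the y axis
#'
#' Inclusive pixel count \code{max(y) - min(y) + 1} over the foot's point
#' set.
#'
#' @param points n x 2 matrix of (x, y) points.
#' @return named numeric vector (yMin, yMax, length).
#' @export
footLength <- function(points) {
  if (is.null(nrow(points)) || nrow(points) == 0)
    stop("empty point set", call. = FALSE)
  y <- points[, 2]
  c(yMin = min(y), yMax = max(y), length = max(y) - min(y) + 1)
}

#' Proportional band lengths (30/30/40)
#'
#' Splits the foot length into forefoot, arch and heel bands of 30, 30 and
#' 40 percent. Non-integer lengths are resolved by flooring the forefoot and
#' arch bands and assigning the remainder to the heel (the largest band), so
#' the three bands always sum to the foot length exactly.
#'
#' @param leftL foot length in pixels, at least 3.
#' @return named integer vector (fore, arch, heel). A zero-length band (only
#'   possible for leftL = 3) is returned as-is and rejected downstream by
#'   \code{\link{buildPartition}}.
#' @export
bandLengths <- function(leftL) {
  if (leftL < 3) stop("degenerate foot: length < 3 px", call. = FALSE)
  fore <- floor(leftL * 0.3)
  arch <- floor(leftL * 0.3)
  c(fore = as.integer(fore), arch = as.integer(arch),
    heel = as.integer(leftL - fore - arch))
}

#' Build the four-region partition of one foot
#'
#' Applies the proportional geometric rule to a toe-excluded point set:
#' the foot length is banded 30/30/40 top-down into forefoot, arch and heel;
#' each band's x extent is the min/max x of the points whose y falls in the
#' band (fore: \code{[yMin, yMin+fore)}; arch: the next \code{arch} rows;
#' heel: the rest through \code{yMax}); the forefoot band is split at
#' \code{foreMin + floor((foreMax - foreMin) / 2)}. For the left foot the
#' lower-x (lateral) forefoot half is the outer forefoot; for the right foot
#' the assignment is mirrored (lower-x half = inner forefoot). Rectangles
#' are half-open; the forefoot halves share the split column.
#'
#' @param points n x 2 matrix of (x, y) contour points of one foot.
#' @param side "left" or "right".
#' @return a \linkS4class{FootPartition}.
#' @export
buildPartition <- function(points, side = c("left", "right")) {
  side <- match.arg(side)
  fl <- footLength(points)
  bands <- bandLengths(fl["length"])
  if (any(bands == 0))
    stop("degenerate foot: a band has zero length", call. = FALSE)
  yMin <- fl[["yMin"]]; yMax <- fl[["yMax"]]
  y <- points[, 2]; x <- points[, 1]
  inFore <- y >= yMin & y < yMin + bands["fore"]
  inArch <- y >= yMin + bands["fore"] & y < yMin + bands["fore"] + bands["arch"]
  inHeel <- y >= yMin + bands["fore"] + bands["arch"] & y <= yMax
  for (nm in c("fore", "arch", "heel")) {
    sel <- switch(nm, fore = inFore, arch = inArch, heel = inHeel)
    if (!any(sel))
      stop("incomplete foot: no points in the ", nm, " band", call. = FALSE)
  }
  ext <- c(
    foreMin = min(x[inFore]), foreMax = max(x[inFore]),
    archMin = min(x[inArch]), archMax = max(x[inArch]),
    heelMin = min(x[inHeel]), heelMax = max(x[inHeel])
  )
  span <- ext[["foreMax"]] - ext[["foreMin"]]
  # forefoot split at foreMin + floor(span/2) on the left foot; the right
  # foot uses the mirrored rule foreMax - floor(span/2) so that a mirrored
  # point set yields the exactly mirrored partition (for even spans the two
  # coincide)
  xm <- if (side == "left") ext[["foreMin"]] + floor(span / 2) else
    ext[["foreMax"]] - floor(span / 2)
  # inclusive column ranges [a, b] stored as half-open rects (w = b - a + 1);
  # the two forefoot halves share the split column xm
  lowHalf <- c(ext[["foreMin"]], xm)
  highHalf <- c(xm, ext[["foreMax"]])
  if (side == "left") {
    outerX <- lowHalf; innerX <- highHalf  # lateral = low x on a left foot
  } else {
    outerX <- highHalf; innerX <- lowHalf
  }
  yFore <- yMin
  yArch <- yMin + bands[["fore"]]
  yHeel <- yArch + bands[["arch"]]
  regions <- data.frame(
    label = regionLabels(),
    x = c(outerX[1], innerX[1], ext[["archMin"]], ext[["heelMin"]]),
    y = c(yFore, yFore, yArch, yHeel),
    w = c(outerX[2] - outerX[1] + 1, innerX[2] - innerX[1] + 1,
      ext[["archMax"]] - ext[["archMin"]] + 1,
      ext[["heelMax"]] - ext[["heelMin"]] + 1),
    h = c(bands[["fore"]], bands[["fore"]], bands[["arch"]],
      bands[["heel"]]),
    stringsAsFactors = FALSE
  )
  new("FootPartition", side = side,
    footLength = as.integer(fl[["length"]]),
    bands = stats::setNames(as.integer(bands), names(bands)),
    yRange = c(ymin = as.integer(yMin), ymax = as.integer(yMax)),
    xExtents = stats::setNames(as.integer(ext), names(ext)),
    regions = regions)
}

#' Arch index of a toe-excluded footprint
#'
#' Splits the footprint into equal y-thirds and reports the ratio of points
#' in the middle third to all points. Intended for filled footprint pixels
#' (an area ratio), not contour outlines alone. Classification thresholds:
#' high arch when AI <= 0.21, normal when 0.21 < AI < 0.26, flat when
#' AI >= 0.26.
#'
#' @param points n x 2 matrix of (x, y) footprint pixels, toes excluded.
#' @return list with \code{ai} (ratio in [0, 1]) and \code{category}
#'   ("high_arch", "normal" or "flat").
#' @export
archIndex <- function(points) {
  if (is.null(nrow(points)) || nrow(points) == 0)
    stop("empty point set", call. = FALSE)
  y <- points[, 2]
  yMin <- min(y); L <- max(y) - yMin + 1
  mid <- y >= yMin + L / 3 & y < yMin + 2 * L / 3
  ai <- sum(mid) / length(y)
  category <- if (ai <= 0.21) "high_arch" else if (ai < 0.26) "normal"
    else "flat"
  list(ai = ai, category = category)
}
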