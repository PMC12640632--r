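#' Quadtree region split-and-merge segmentation
#'
#' Splits the image by a quadtree until every block is homogeneous
#' (intensity range at most \code{tol}) or reaches side \code{minRegion},
#' then iteratively merges 4-adjacent regions whose union stays homogeneous,
#' restarting the scan after every merge (equivalently: always merging the
#' eligible pair with the smallest creation ids, since a region's range only
#' grows). A pixel is marked as region boundary/foreground (255) when its
#' final region's mean intensity lies strictly inside
#' \code{(minThresh, maxThresh)}, else background (0).
#'
#' Images are padded to the next power-of-two square (with zeros) so that
#' "four equal sub-regions" always divide evenly, and cropped back.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param minRegion smallest splittable block side (power of two).
#' @param tol homogeneity tolerance: maximum intensity range of a region.
#' @param minThresh,maxThresh open interval of region mean intensities
#'   marked as foreground; the reference pipeline uses (50, 100).
#' @return a \linkS4class{BinaryMask}.
#' @seealso \code{\link{splitRegions}} for the intermediate region map.
#' @export
splitMerge <- function(img, minRegion = 4, tol = 16, minThresh = 50,
                       maxThresh = 100) {
  .assertImage(img)
  if (minThresh >= maxThresh) stop("minThresh must be < maxThresh")
  sm <- .splitMergeRegions(pixels(img), minRegion, tol, doMerge = TRUE)
  means <- sm$stats[, "mean"][match(sm$labels, sm$stats[, "id"])]
  fg <- means > minThresh & means < maxThresh
  BinaryMask(matrix(fg, nrow(sm$labels), ncol(sm$labels)) * 255L)
}

#' Region map of the split (and optional merge) phase
#'
#' Exposes the quadtree leaves before merging, or the merged region map, for
#' inspection and testing.
#'
#' @inheritParams splitMerge
#' @param merge run the merge phase.
#' @return list with \code{labels} (integer matrix of region ids, creation
#'   order) and \code{stats} (matrix with columns id, min, max, mean, count,
#'   one row per surviving region).
#' @export
splitRegions <- function(img, minRegion = 4, tol = 16, merge = FALSE) {
  .assertImage(img)
  .splitMergeRegions(pixels(img), minRegion, tol, doMerge = merge)
}

.splitMergeRegions <- function(p, minRegion, tol, doMerge) {
  stopifnot(minRegion >= 1, tol >= 0)
  size <- 2^ceiling(log2(max(dim(p), 1)))
  if (bitwAnd(minRegion, minRegion - 1L) != 0)
    stop("minRegion must be a power of two", call. = FALSE)
  pad <- matrix(0L, size, size)
  pad[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  res <- cpp_split_merge(pad, as.integer(minRegion), tol, doMerge)
  labels <- res$labels[seq_len(nrow(p)), seq_len(ncol(p)), drop = FALSE]
  # stats refer to the padded support; regions entirely inside the pad are
  # dropped after cropping
  stats <- res$stats[res$stats[, "id"] %in% unique(as.vector(labels)), ,
    drop = FALSE]
  list(labels = labels, stats = stats)
}
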