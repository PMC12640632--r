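#' Intersection over union of two pixel rectangles
#'
#' Exact pixel-count IoU under the half-open rectangle convention; 0 for
#' disjoint boxes, 1 for identical boxes.
#'
#' @param a,b rectangles as named vectors/lists with x, y, w, h.
#' @return ratio in [0, 1].
#' @export
iouRect <- function(a, b) {
  ix <- max(0, min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]) -
    max(a[["x"]], b[["x"]]))
  iy <- max(0, min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]) -
    max(a[["y"]], b[["y"]]))
  inter <- ix * iy
  uni <- a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter
  inter / uni
}

#' Qualitative performance band of an IoU score
#'
#' poor when IoU < 0.6; good when 0.6 <= IoU < 0.90; excellent when
#' IoU >= 0.90.
#'
#' @param iou ratio in [0, 1].
#' @return "poor", "good" or "excellent" (vectorized).
#' @export
performanceBand <- function(iou) {
  if (any(iou < 0 | iou > 1)) stop("IoU out of [0, 1]", call. = FALSE)
  ifelse(iou >= 0.90, "excellent", ifelse(iou >= 0.6, "good", "poor"))
}

# per-image IoU rows for every ground-truth cell (side x label), joining a
# single-proposal prediction table; a missing prediction scores IoU 0
.iouTable <- function(pred, gt) {
  key <- function(d) paste(d$image, d$side, d$label, sep = "\r")
  pk <- key(pred)
  ious <- numeric(nrow(gt))
  matched <- logical(nrow(pred))
  m <- match(key(gt), pk)
  for (i in seq_len(nrow(gt))) {
    if (is.na(m[i])) { ious[i] <- 0; next }
    matched[m[i]] <- TRUE
    ious[i] <- iouRect(pred[m[i], ], gt[i, ])
  }
  list(
    rows = data.frame(image = gt$image, side = gt$side, label = gt$label,
      iou = ious, predicted = !is.na(m), stringsAsFactors = FALSE),
    spurious = pred[!matched, , drop = FALSE]  # pred cells without gt: FPs
  )
}

#' Average precision of single-proposal detections
#'
#' The region partitioner proposes exactly one box per region per foot per
#' image, so AP reduces to a sweep over IoU thresholds: at each threshold a
#' prediction is a true positive iff its IoU with the same-side, same-label
#' ground truth reaches the threshold (otherwise a false positive); a
#' ground-truth box without a prediction is a false negative; a prediction
#' without ground truth a false positive. AP is the mean precision over the
#' thresholds, and mAP the mean AP over the side-by-region cells.
#'
#' @param pred data.frame of predictions: image, side, label, x, y, w, h.
#' @param gt data.frame of ground truth, same columns.
#' @param iouThresholds IoU threshold grid (default the COCO-style grid
#'   0.50, 0.55, ..., 0.95; use a single value for AP at IoU 0.5).
#' @return list with \code{perRegion} (data.frame side, label, ap, meanIoU),
#'   \code{map} (mean AP over cells) and \code{iouThresholds}.
#' @export
averagePrecision <- function(pred, gt,
                             iouThresholds = seq(0.5, 0.95, by = 0.05)) {
  it <- .iouTable(pred, gt)
  rows <- it$rows
  cells <- unique(rbind(gt[, c("side", "label")],
    it$spurious[, c("side", "label")]))
  cells <- cells[order(cells$side, match(cells$label, regionLabels())), ,
    drop = FALSE]
  ap <- numeric(nrow(cells))
  miou <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- rows[rows$side == cells$side[i] & rows$label == cells$label[i], ]
    nspur <- sum(it$spurious$side == cells$side[i] &
      it$spurious$label == cells$label[i])
    prec <- vapply(iouThresholds, function(t) {
      tp <- sum(r$predicted & r$iou >= t)
      fp <- sum(r$predicted & r$iou < t) + nspur
      if (tp + fp == 0) 0 else tp / (tp + fp)
    }, numeric(1))
    ap[i] <- mean(prec)
    miou[i] <- if (nrow(r)) mean(r$iou) else 0
  }
  list(
    perRegion = data.frame(side = cells$side, label = cells$label, ap = ap,
      meanIoU = miou, stringsAsFactors = FALSE),
    map = mean(ap),
    iouThresholds = iouThresholds
  )
}

#' Two-step grouped evaluation report
#'
#' Scores predictions against ground truth with the two-step aggregation of
#' the reference protocol: metrics are first averaged within the normal and
#' abnormal groups, then the two group means are averaged (unweighted) for
#' the final value. Pooled (per-image weighted) means are also reported for
#' transparency. When one group is empty the report marks it absent, warns,
#' and uses the other group's mean as final.
#'
#' @param pred data.frame of predictions: image, side, label, x, y, w, h.
#' @param gt data.frame of ground truth, same columns.
#' @param groups data.frame with columns image and group
#'   ("normal"/"abnormal").
#' @param iouThresholds AP threshold grid, as in
#'   \code{\link{averagePrecision}}.
#' @return an \linkS4class{EvalReport}.
#' @export
groupedReport <- function(pred, gt, groups,
                          iouThresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(all(c("image", "group") %in% names(groups)))
  gt$group <- groups$group[match(gt$image, groups$image)]
  if (anyNA(gt$group)) stop("every image needs a normal/abnormal group tag")
  pred$group <- groups$group[match(pred$image, groups$image)]
  present <- intersect(c("normal", "abnormal"), unique(gt$group))
  if (length(present) < 2)
    warning("group(s) absent: ",
      paste(setdiff(c("normal", "abnormal"), present), collapse = ", "),
      "; final values equal the present group's mean")

  perGroup <- lapply(present, function(g) {
    averagePrecision(pred[!is.na(pred$group) & pred$group == g, ,
      drop = FALSE], gt[gt$group == g, , drop = FALSE], iouThresholds)
  })
  names(perGroup) <- present
  pooled <- averagePrecision(pred, gt, iouThresholds)

  cells <- pooled$perRegion[, c("side", "label")]
  getCol <- function(g, col) {
    pr <- perGroup[[g]]$perRegion
    pr[[col]][match(paste(cells$side, cells$label),
      paste(pr$side, pr$label))]
  }
  asMat <- function(col) matrix(
    unlist(lapply(present, getCol, col = col)),
    nrow = nrow(cells), dimnames = list(NULL, present))
  iouG <- asMat("meanIoU")
  apG <- asMat("ap")
  meanIoU2 <- rowMeans(iouG, na.rm = TRUE)
  ap2 <- rowMeans(apG, na.rm = TRUE)

  perRegion <- data.frame(cells,
    meanIoU = meanIoU2, ap = ap2,
    iouPooled = pooled$perRegion$meanIoU, apPooled = pooled$perRegion$ap,
    band = performanceBand(pmin(pmax(meanIoU2, 0), 1)),
    stringsAsFactors = FALSE)
  for (g in present) {
    perRegion[[paste0("iou_", g)]] <- iouG[, g]
    perRegion[[paste0("ap_", g)]] <- apG[, g]
  }

  it <- .iouTable(pred, gt)
  fails <- it$rows[!it$rows$predicted, c("image", "side", "label"),
    drop = FALSE]

  gm <- data.frame(
    group = c(present, "overall"),
    meanIoU = c(vapply(present,
      function(g) mean(perGroup[[g]]$perRegion$meanIoU), numeric(1)),
      mean(meanIoU2)),
    mAP = c(vapply(present, function(g) perGroup[[g]]$map, numeric(1)),
      mean(ap2)),
    stringsAsFactors = FALSE)

  new("EvalReport", perRegion = perRegion, meanIoU = mean(meanIoU2),
    mapScore = mean(ap2), groupMeans = gm, failures = fails,
    protocol = list(iouThresholds = iouThresholds,
      aggregation = "two-step normal/abnormal"))
}
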