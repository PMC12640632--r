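#' Run the hybrid segmentation pipeline
#'
#' Per image: segmentation backend, border-following contour extraction,
#' shoelace-area filtering (toe exclusion), left/right assignment, and the
#' proportional geometric partition of each detected foot. Images with no
#' surviving contour, or feet whose bands are empty, are recorded as failed
#' samples and the run continues.
#'
#' @param images character vector of image paths, a list of
#'   \linkS4class{PressureImage} objects, or a list of samples from
#'   \code{\link{generateFootprint}}.
#' @param method segmentation backend ("canny", "threshold", "splitmerge").
#' @param params backend parameter overrides (see
#'   \code{\link{segmentationPresets}}).
#' @param minArea strict contour-area filter in squared pixels.
#' @param archIndexFill intensity above which a pixel counts as footprint
#'   contact for the optional arch-index computation; NULL disables it.
#' @param ids image identifiers used in the prediction table (defaults to
#'   file names or list indices).
#' @return list with \code{predictions} (data.frame image, side, label, x,
#'   y, w, h), \code{failures} (data.frame image, side, reason),
#'   \code{archIndex} (data.frame, when enabled) and \code{counts}
#'   (per-image contour statistics).
#' @export
runPipeline <- function(images, method = "canny", params = list(),
                        minArea = 6000, archIndexFill = NULL, ids = NULL) {
  getImage <- function(el) {
    if (is.character(el)) readPressureImage(el)
    else if (methods::is(el, "PressureImage")) el
    else if (is.list(el) && methods::is(el$image, "PressureImage")) el$image
    else stop("unsupported image input", call. = FALSE)
  }
  n <- length(images)
  if (is.null(ids)) {
    ids <- if (is.character(images)) basename(images) else
      sprintf("img%04d", seq_len(n))
  }
  preds <- list(); fails <- list(); ais <- list(); counts <- list()
  for (i in seq_len(n)) {
    el <- if (is.character(images)) images[i] else images[[i]]
    img <- getImage(el)
    mask <- segmentImage(img, method = method, params = params)
    cs <- traceContours(mask)
    kept <- filterByArea(cs, minArea)
    regions <- assignRegions(kept, imgWidth(img))
    counts[[i]] <- data.frame(image = ids[i], contoursFound = length(cs),
      contoursKept = length(kept), feet = length(unique(regions$side)),
      stringsAsFactors = FALSE)
    if (nrow(regions) == 0) {
      fails[[length(fails) + 1]] <- data.frame(image = ids[i], side = NA,
        reason = "no contour above minArea", stringsAsFactors = FALSE)
      next
    }
    for (s in unique(regions$side)) {
      res <- tryCatch({
        pts <- collectFootPoints(kept, regions, s)
        part <- buildPartition(pts, side = s)
        b <- part@regions
        list(part = part, boxes = data.frame(image = ids[i], side = s,
          label = b$label, x = b$x, y = b$y, w = b$w, h = b$h,
          stringsAsFactors = FALSE))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- data.frame(image = ids[i], side = s,
          reason = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      preds[[length(preds) + 1]] <- res$boxes
      if (!is.null(archIndexFill)) {
        part <- res$part
        p <- pixels(img)
        yr <- part@yRange; xr <- range(part@regions$x,
          part@regions$x + part@regions$w - 1)
        sub <- p[(yr["ymin"]:yr["ymax"]) + 1L, (xr[1]:xr[2]) + 1L,
          drop = FALSE]
        fill <- which(sub > archIndexFill, arr.ind = TRUE)
        if (nrow(fill)) {
          aiRes <- archIndex(cbind(x = fill[, 2] - 1L + xr[1],
            y = fill[, 1] - 1L + yr["ymin"]))
          ais[[length(ais) + 1]] <- data.frame(image = ids[i], side = s,
            ai = aiRes$ai, category = aiRes$category,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  bindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else
    proto
  list(
    predictions = bindOr(preds, data.frame(image = character(0),
      side = character(0), label = character(0), x = numeric(0),
      y = numeric(0), w = numeric(0), h = numeric(0))),
    failures = bindOr(fails, data.frame(image = character(0),
      side = character(0), reason = character(0))),
    archIndex = bindOr(ais, data.frame(image = character(0),
      side = character(0), ai = numeric(0), category = character(0))),
    counts = bindOr(counts, data.frame(image = character(0),
      contoursFound = integer(0), contoursKept = integer(0),
      feet = integer(0)))
  )
}

#' Benchmark segmentation backends on a synthetic dataset
#'
#' Streams over a dataset manifest (re-generating each sample from its
#' recorded seed), runs the requested backends through the full hybrid
#' pipeline, and scores each against the programmatic ground truth with the
#' two-step normal/abnormal evaluation. Incomplete samples whose true
#' geometry cannot be partitioned are skipped (they carry no ground truth).
#'
#' @param manifest manifest from \code{\link{generateDataset}} (or a list of
#'   pre-generated samples).
#' @param methods backends to compare.
#' @param minArea contour-area filter.
#' @param iouThresholds AP protocol grid.
#' @param verbose print per-method progress.
#' @return list with \code{reports} (named list of
#'   \linkS4class{EvalReport}), \code{table} (long data.frame side x label x
#'   method with meanIoU, ap and band) and \code{gt}, \code{predictions}.
#' @export
compareMethods <- function(manifest,
                           methods = c("threshold", "splitmerge", "canny"),
                           minArea = 6000,
                           iouThresholds = seq(0.5, 0.95, by = 0.05),
                           verbose = FALSE) {
  isManifest <- is.data.frame(manifest)
  n <- if (isManifest) nrow(manifest) else length(manifest)
  ids <- sprintf("img%04d", seq_len(n))
  gts <- list()
  predsByMethod <- stats::setNames(
    replicate(length(methods), list(), simplify = FALSE), methods)
  failsByMethod <- stats::setNames(
    replicate(length(methods), list(), simplify = FALSE), methods)
  groups <- character(n)
  for (i in seq_len(n)) {
    smp <- if (isManifest) manifestSample(manifest, i) else manifest[[i]]
    groups[i] <- if (isManifest) manifest$group[i] else
      if (smp$meta$spec@footType == "normal") "normal" else "abnormal"
    if (nrow(smp$gtBoxes) == 0) next
    g <- smp$gtBoxes
    g$image <- ids[i]
    gts[[length(gts) + 1]] <- g
    for (m in methods) {
      run <- runPipeline(list(smp), method = m, minArea = minArea,
        ids = ids[i])
      if (nrow(run$predictions))
        predsByMethod[[m]][[length(predsByMethod[[m]]) + 1]] <-
          run$predictions
      if (nrow(run$failures))
        failsByMethod[[m]][[length(failsByMethod[[m]]) + 1]] <-
          run$failures
    }
    if (verbose && i %% 25 == 0) message("  processed ", i, "/", n)
  }
  gt <- do.call(rbind, gts)
  groupTab <- data.frame(image = ids, group = groups,
    stringsAsFactors = FALSE)
  reports <- list(); tabs <- list()
  for (m in methods) {
    pred <- if (length(predsByMethod[[m]]))
      do.call(rbind, predsByMethod[[m]]) else
      data.frame(image = character(0), side = character(0),
        label = character(0), x = numeric(0), y = numeric(0),
        w = numeric(0), h = numeric(0))
    rep <- groupedReport(pred, gt, groupTab, iouThresholds)
    reports[[m]] <- rep
    tabs[[m]] <- data.frame(method = m,
      rep@perRegion[, c("side", "label", "meanIoU", "ap", "band")],
      stringsAsFactors = FALSE)
  }
  list(reports = reports, table = do.call(rbind, tabs), gt = gt,
    predictions = predsByMethod)
}
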