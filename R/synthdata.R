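#' Specify a synthetic plantar pressure image
#'
#' Builds a validated \linkS4class{SynthSpec}. Per-type defaults for the
#' midfoot contact fraction follow the morphology definitions: a normal foot
#' has roughly half its midfoot width in contact (0.5), a low arch nearly
#' full contact (0.9) and a high arch minimal contact (0.1); the two
#' heel-tilt types use the normal midfoot but deviate the calcaneus and
#' alter which toes register (inward tilt drops the hallux, outward tilt
#' keeps only the hallux).
#'
#' @param footType one of \code{\link{footTypes}()}.
#' @param side "both" (default: a left and a right footprint in one image),
#'   "left" or "right".
#' @param imageSize integer (width, height), default 700 x 700.
#' @param footLength sole length (toes excluded) in pixels.
#' @param midfootContact contact fraction in [0, 1]; NULL = per-type default.
#' @param completeness "complete", "missing_toes" or "incomplete" (a band of
#'   the sole is erased).
#' @param noiseSd standard deviation of the sensor-grid noise (intensity
#'   units on the 120 x 120 acquisition grid).
#' @param seed integer seed; NA leaves the RNG state alone.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(footType = "normal", side = "both",
                      imageSize = c(700L, 700L),
                      footLength = round(0.6 * imageSize[2]),
                      midfootContact = NULL,
                      completeness = "complete", noiseSd = 8,
                      seed = NA_integer_) {
  defaults <- c(normal = 0.5, low_arch = 0.9, high_arch = 0.1,
    inward_tilt = 0.5, outward_tilt = 0.5)
  if (is.null(midfootContact)) midfootContact <- unname(defaults[footType])
  new("SynthSpec", footType = footType, side = side,
    imageSize = as.integer(imageSize), footLength = as.integer(footLength),
    midfootContact = as.numeric(midfootContact),
    completeness = completeness, noiseSd = as.numeric(noiseSd),
    seed = as.integer(seed))
}

# outline half-width profiles (fraction of sole length) at knot positions of
# the normalized sole coordinate t in [0, 1] (0 = toe end of the sole)
.soleKnots <- function() {
  list(
    t = c(0, 0.16, 0.30, 0.52, 0.72, 0.85, 1),
    lateral = c(0.030, 0.175, 0.150, 0.112, 0.125, 0.135, 0.030),
    medial = c(0.030, 0.165, 0.140, 0.120, 0.100, 0.115, 0.030)
  )
}

# arch cut activation: 0 outside the midfoot, 1 in its core
.archBump <- function(t) {
  .smoothstep(t, 0.30, 0.40) * (1 - .smoothstep(t, 0.62, 0.73))
}

# left-foot geometry on its own canvas (halfW x H); medial side is +x
.footGeometry <- function(spec, halfW, H) {
  L <- spec@footLength
  y0 <- round((H - 1.18 * L) / 2 + 0.15 * L)
  xc <- halfW / 2
  kn <- .soleKnots()
  ql <- stats::splinefun(kn$t, kn$lateral, method = "natural")
  qm <- stats::splinefun(kn$t, kn$medial, method = "natural")

  tilt <- switch(spec@footType, inward_tilt = 1, outward_tilt = -1, 0)
  sole <- matrix(FALSE, H, halfW)
  rows <- seq.int(y0, y0 + L - 1)
  tt <- (rows - y0) / (L - 1)
  off <- tilt * 0.06 * L * .smoothstep(tt, 0.65, 0.95)
  xl <- xc + off - L * pmax(ql(tt), 0.005)
  xr <- xc + off + L * pmax(qm(tt), 0.005)
  ceff <- 1 - (1 - spec@midfootContact) * .archBump(tt)
  xk <- xl + ceff * (xr - xl)
  for (i in seq_along(rows)) {
    a <- max(1L, as.integer(ceiling(xl[i])) + 1L) # 0-based -> 1-based cols
    b <- min(halfW, as.integer(floor(xk[i])) + 1L)
    if (b >= a) sole[rows[i] + 1L, a:b] <- TRUE
  }

  toes <- matrix(FALSE, H, halfW)
  toeSet <- if (spec@completeness == "missing_toes") character(0)
    else switch(spec@footType,
      inward_tilt = paste0("t", 1:4),
      outward_tilt = "hallux",
      c("hallux", paste0("t", 1:4)))
  toeDefs <- list(
    hallux = c(dx = 0.080, dy = -0.075, a = 0.042, b = 0.050),
    t1 = c(dx = 0.022, dy = -0.068, a = 0.027, b = 0.029),
    t2 = c(dx = -0.034, dy = -0.060, a = 0.025, b = 0.027),
    t3 = c(dx = -0.088, dy = -0.052, a = 0.023, b = 0.025),
    t4 = c(dx = -0.138, dy = -0.044, a = 0.021, b = 0.023)
  )
  if (length(toeSet)) {
    xg <- matrix(rep(0:(halfW - 1), each = H), H, halfW)
    yg <- matrix(rep(0:(H - 1), halfW), H, halfW)
    for (nm in toeSet) {
      d <- toeDefs[[nm]]
      cx <- xc + d["dx"] * L
      cy <- y0 + d["dy"] * L
      toes <- toes | ((xg - cx) / (d["a"] * L))^2 +
        ((yg - cy) / (d["b"] * L))^2 <= 1
    }
  }

  if (spec@completeness == "incomplete") {
    ys <- y0 + round(stats::runif(1, 0.35, 0.55) * L)
    cut <- seq.int(ys, min(ys + round(0.10 * L), H - 1)) + 1L
    sole[cut, ] <- FALSE
  }
  list(sole = sole, toes = toes, y0 = y0, L = L)
}

# pressure field: distance-transform-shaped intensity. The sole margin
# carries low-but-sharp contact pressure (~122 with the sensor baseline)
# that climbs through the simple-threshold level 127 a few pixels inside
# (real footprints bear less load at the margins); high-contact rims at the
# toe end and the heel cap rise steeply so the strongest gradients sit on
# the outer contour.
.pressureField <- function(geom, halfW, H) {
  fg <- geom$sole | geom$toes
  d <- EBImage::distmap(matrix(as.numeric(fg), H, halfW))
  d <- as.numeric(d)
  dim(d) <- c(H, halfW)
  taper <- 120 + 2 * pmin(d, 6) + 105 * pmin(pmax(d - 6, 0) / 22, 1)^0.8
  rim <- 150 + 105 * pmin(d / 3, 1)^0.7
  tt <- pmin(pmax((matrix(rep(0:(H - 1), halfW), H, halfW) - geom$y0) /
    (geom$L - 1), 0), 1)
  w <- (1 - .smoothstep(tt, 0.05, 0.14)) + .smoothstep(tt, 0.82, 0.93)
  v <- (1 - w) * taper + w * rim
  vtoe <- 150 + 80 * pmin(d / 4, 1)
  out <- matrix(0, H, halfW)
  out[geom$sole] <- v[geom$sole]
  out[geom$toes] <- vtoe[geom$toes]
  out
}

# smooth sensor noise: white noise on the acquisition grid, bilinearly
# upsampled to pixel resolution (the scanner interpolates a 120x120 array
# up to 700x700, so pixel noise is spatially correlated at the sensor
# pitch). The caller scales the field by the local signal: piezoresistive
# cells fluctuate in proportion to the load they carry, and unloaded cells
# read near zero.
.sensorNoise <- function(H, W, sd, gridSize = 120) {
  if (sd <= 0) return(matrix(0, H, W))
  g <- matrix(stats::rnorm(gridSize^2, sd = sd), gridSize, gridSize)
  .bilinear(g, H, W)
}

.bilinear <- function(g, nr, nc) {
  ri <- seq(1, nrow(g), length.out = nr)
  ci <- seq(1, ncol(g), length.out = nc)
  r0 <- pmin(floor(ri), nrow(g) - 1); rf <- ri - r0
  c0 <- pmin(floor(ci), ncol(g) - 1); cf <- ci - c0
  outer(1 - rf, 1 - cf) * g[r0, c0] + outer(rf, 1 - cf) * g[r0 + 1, c0] +
    outer(1 - rf, cf) * g[r0, c0 + 1] + outer(rf, cf) * g[r0 + 1, c0 + 1]
}

#' Generate one synthetic plantar pressure image
#'
#' Composes a parametric footprint (smooth sole outline with a
#' contact-controlled arch cut, plus disconnected toe blobs), shapes the
#' pressure field by the distance transform of the noise-free geometry, adds
#' a small sensor baseline and spatially correlated sensor-grid noise, and
#' quantizes to 8 bits. Ground-truth region boxes are obtained by applying
#' the proportional partition rule to the true noise-free sole geometry, so
#' downstream scores measure recovery of known geometry through noise and
#' segmentation.
#'
#' @param spec a \linkS4class{SynthSpec} (or arguments forwarded to
#'   \code{\link{synthSpec}} when \code{spec} is a foot-type string).
#' @return list with elements \code{image} (\linkS4class{PressureImage}),
#'   \code{gtBoxes} (data.frame side, label, x, y, w, h; empty when the
#'   geometry is too fragmented to partition), \code{gtMask} (integer matrix
#'   of region codes 1-8, side-major as in \code{\link{gtClassMap}}), and
#'   \code{meta} (list: spec plus per-side true geometry).
#' @export
generateFootprint <- function(spec = synthSpec()) {
  if (is.character(spec)) spec <- synthSpec(footType = spec)
  methods::validObject(spec)
  if (!is.na(spec@seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(spec@seed)
  }
  W <- spec@imageSize[1]; H <- spec@imageSize[2]
  sides <- if (spec@side == "both") c("left", "right") else spec@side
  halfW <- if (spec@side == "both") W %/% 2L else W

  field <- matrix(0, H, W)
  gtMask <- matrix(0L, H, W)
  gtBoxes <- .emptyGt()
  meta <- list(spec = spec, geometry = list())
  for (s in sides) {
    geom <- .footGeometry(spec, halfW, H)
    v <- .pressureField(geom, halfW, H)
    mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (s == "right") {
      v <- mirror(v)
      geom$sole <- mirror(geom$sole)
      geom$toes <- mirror(geom$toes)
    }
    xoff <- if (spec@side == "both" && s == "right") W - halfW else 0L
    cols <- xoff + seq_len(halfW)
    field[, cols] <- pmax(field[, cols], v)

    solePix <- which(geom$sole, arr.ind = TRUE)
    pts <- cbind(x = solePix[, 2] - 1L + xoff, y = solePix[, 1] - 1L)
    part <- tryCatch(buildPartition(pts, side = s), error = function(e) NULL)
    meta$geometry[[s]] <- list(nSolePx = nrow(pts),
      footLength = if (is.null(part)) NA_integer_ else part@footLength,
      partitioned = !is.null(part))
    if (!is.null(part)) {
      b <- part@regions
      b <- data.frame(side = s, label = b$label, x = b$x, y = b$y, w = b$w,
        h = b$h, stringsAsFactors = FALSE)
      gtBoxes <- rbind(gtBoxes, b)
      base <- if (s == "left") 0L else 4L
      codes <- stats::setNames(base + 1:4, regionLabels())
      for (k in seq_len(nrow(b))) {
        sel <- pts[, "y"] >= b$y[k] & pts[, "y"] < b$y[k] + b$h[k] &
          pts[, "x"] >= b$x[k] & pts[, "x"] < b$x[k] + b$w[k]
        gtMask[cbind(pts[sel, "y"] + 1L, pts[sel, "x"] + 1L)] <-
          codes[[b$label[k]]]
      }
    }
  }
  noise <- .sensorNoise(H, W, spec@noiseSd) * pmin(field / 255, 1)
  img <- pmin(pmax(round(field + 2 + noise), 0), 255)
  list(image = PressureImage(matrix(as.integer(img), H, W)),
    gtBoxes = gtBoxes, gtMask = gtMask, meta = meta)
}

#' Generate a benchmark dataset of synthetic footprints
#'
#' Apportions \code{n} samples over the five foot types by largest-remainder
#' rounding of \code{mix} (default composition: 40 percent normal feet and
#' 15 percent of each abnormal type, i.e. 80 + 4 x 30 at n = 200), draws
#' per-sample foot length and contact jitter from a seeded RNG, and returns
#' a manifest. With \code{outDir} set, images (PNG), ground truth (YOLO txt
#' and JSON) and \code{manifest.csv} are written; otherwise the manifest
#' alone is returned and samples are re-generated on demand from their
#' recorded per-sample seeds (see \code{\link{manifestSample}}).
#'
#' @param n number of images, at least 5.
#' @param mix named type proportions (normalized internally).
#' @param seed master seed; every stochastic draw descends from it.
#' @param outDir optional output directory.
#' @param imageSize,noiseSd,completeness forwarded to
#'   \code{\link{synthSpec}}.
#' @return data.frame manifest: id, type, group, side, footLength,
#'   midfootContact, completeness, noiseSd, seed, and file columns when
#'   \code{outDir} is set.
#' @export
generateDataset <- function(n, mix = c(normal = 0.40, low_arch = 0.15,
                              high_arch = 0.15, inward_tilt = 0.15,
                              outward_tilt = 0.15),
                            seed = 1, outDir = NULL,
                            imageSize = c(700L, 700L), noiseSd = 8,
                            completeness = "complete") {
  if (n < 5) stop("n must be at least 5 (one sample per foot type)")
  mix <- mix[footTypes()]
  if (anyNA(mix)) stop("mix must name all five foot types")
  mix <- mix / sum(mix)
  quota <- n * mix
  cnt <- floor(quota)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(-(quota - cnt), seq_along(quota)) # ties: type order
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  types <- rep(names(cnt), cnt)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed %% 2147483647)
  H <- imageSize[2]
  defaults <- c(normal = 0.5, low_arch = 0.9, high_arch = 0.1,
    inward_tilt = 0.5, outward_tilt = 0.5)
  man <- data.frame(
    id = seq_len(n),
    type = types,
    group = ifelse(types == "normal", "normal", "abnormal"),
    side = "both",
    footLength = round(stats::runif(n, 0.54, 0.63) * H),
    midfootContact = pmin(pmax(unname(defaults[types]) +
      stats::runif(n, -0.04, 0.04), 0.05), 0.95),
    completeness = completeness,
    noiseSd = noiseSd,
    seed = (seed * 1009 + seq_len(n) * 9973) %% 2147483647,
    stringsAsFactors = FALSE
  )
  attr(man, "imageSize") <- as.integer(imageSize)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outDir, call. = FALSE)
    man$file <- file.path(outDir, sprintf("img_%04d.png", man$id))
    man$gtYolo <- file.path(outDir, sprintf("gt_%04d.txt", man$id))
    man$gtJson <- file.path(outDir, sprintf("gt_%04d.json", man$id))
    for (i in seq_len(n)) {
      smp <- manifestSample(man, i)
      writePressureImage(smp$image, man$file[i])
      writeGroundTruth(smp$gtBoxes, man$gtYolo[i], imageSize[1], imageSize[2])
      writeGroundTruth(smp$gtBoxes, man$gtJson[i], imageSize[1], imageSize[2],
        image = basename(man$file[i]))
    }
    utils::write.csv(man, file.path(outDir, "manifest.csv"),
      row.names = FALSE)
  }
  man
}

#' Re-generate one sample recorded in a manifest
#'
#' @param manifest a manifest from \code{\link{generateDataset}}.
#' @param i row index.
#' @return the sample, as from \code{\link{generateFootprint}}.
#' @export
manifestSample <- function(manifest, i) {
  sz <- attr(manifest, "imageSize")
  if (is.null(sz)) sz <- c(700L, 700L)
  generateFootprint(synthSpec(
    footType = manifest$type[i], side = manifest$side[i], imageSize = sz,
    footLength = manifest$footLength[i],
    midfootContact = manifest$midfootContact[i],
    completeness = manifest$completeness[i],
    noiseSd = manifest$noiseSd[i], seed = manifest$seed[i]))
}
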