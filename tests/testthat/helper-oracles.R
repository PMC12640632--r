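# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and first-principles
# definitions, kept slow and obvious.

# exhaustive Otsu: try all 256 cuts, compute between-class variance directly
bruteOtsu <- function(pix) {
  v <- as.vector(pix)
  best <- -Inf; bestT <- NA
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; bestT <- t }
  }
  bestT
}

# boundary pixels of every 8-connected component: foreground pixels with a
# 4-neighbour outside the foreground (or on the image border)
bruteBoundary <- function(mask) {
  fg <- mask > 0
  nr <- nrow(fg); nc <- ncol(fg)
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c]) next
    nb <- c(
      r == 1 || !fg[r - 1, c], r == nr || !fg[r + 1, c],
      c == 1 || !fg[r, c - 1], c == nc || !fg[r, c + 1]
    )
    if (any(nb)) out <- rbind(out, c(x = c - 1L, y = r - 1L))
  }
  out
}

# even-odd ray-casting point-in-polygon (vertices vx, vy; open polygon)
pointInPoly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Pick's theorem area of a simple lattice polygon: I + B/2 - 1
pickArea <- function(poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  B <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    B <- B + .gcd(abs(vx[j] - vx[i]), abs(vy[j] - vy[i]))
  }
  I <- 0L
  for (px in seq(min(vx), max(vx))) for (py in seq(min(vy), max(vy))) {
    if (.onBoundary(px, py, vx, vy)) next
    if (pointInPoly(px, py, vx, vy)) I <- I + 1L
  }
  I + B / 2 - 1
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.onBoundary <- function(px, py, vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
    cross <- dx * (py - vy[i]) - dy * (px - vx[i])
    if (cross == 0 &&
        px >= min(vx[i], vx[j]) && px <= max(vx[i], vx[j]) &&
        py >= min(vy[i], vy[j]) && py <= max(vy[i], vy[j])) return(TRUE)
  }
  FALSE
}

# random star-shaped simple lattice polygon around a centre (resamples until
# rounding to the lattice has not destroyed simplicity)
randomSimplePolygon <- function(nv = 7, radius = 12, centre = c(20, 20)) {
  repeat {
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    if (min(diff(c(ang, ang[1] + 2 * pi))) < 0.25) next
    rad <- stats::runif(nv, radius * 0.5, radius)
    px <- round(centre[1] + rad * cos(ang))
    py <- round(centre[2] + rad * sin(ang))
    keep <- c(TRUE, diff(px) != 0 | diff(py) != 0)
    px <- px[keep]; py <- py[keep]
    n <- length(px)
    if (n >= 4 && !(px[1] == px[n] && py[1] == py[n]) &&
        isSimplePolygon(px, py)) return(cbind(x = px, y = py))
  }
}

isSimplePolygon <- function(px, py) {
  n <- length(px)
  seg <- cbind(i = seq_len(n), j = c(2:n, 1))
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  intersects <- function(a, b, c, d) {
    d1 <- cross2(px[c], py[c], px[d], py[d], px[a], py[a])
    d2 <- cross2(px[c], py[c], px[d], py[d], px[b], py[b])
    d3 <- cross2(px[a], py[a], px[b], py[b], px[c], py[c])
    d4 <- cross2(px[a], py[a], px[b], py[b], px[d], py[d])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (t <= s) next
    a <- seg[s, 1]; b <- seg[s, 2]; c <- seg[t, 1]; d <- seg[t, 2]
    if (length(unique(c(a, b, c, d))) < 4) next # shared vertex: skip
    if (intersects(a, b, c, d)) return(FALSE)
  }
  TRUE
}

# brute-force IoU by explicit pixel membership on a finite grid
bruteIoU <- function(a, b, grid = 40) {
  inA <- 0L; inB <- 0L; inBoth <- 0L
  for (px in 0:(grid - 1)) for (py in 0:(grid - 1)) {
    ia <- px >= a["x"] && px < a["x"] + a["w"] && py >= a["y"] &&
      py < a["y"] + a["h"]
    ib <- px >= b["x"] && px < b["x"] + b["w"] && py >= b["y"] &&
      py < b["y"] + b["h"]
    inA <- inA + ia; inB <- inB + ib; inBoth <- inBoth + (ia && ib)
  }
  inBoth / (inA + inB - inBoth)
}

# naive single-proposal average precision by explicit enumeration
bruteAP <- function(pred, gt, thresholds) {
  prec <- sapply(thresholds, function(t) {
    tp <- 0L; fp <- 0L
    for (i in seq_len(nrow(pred))) {
      g <- gt[gt$image == pred$image[i] & gt$side == pred$side[i] &
        gt$label == pred$label[i], ]
      if (nrow(g) == 0) { fp <- fp + 1L; next }
      iou <- iouRect(pred[i, ], g[1, ])
      if (iou >= t) tp <- tp + 1L else fp <- fp + 1L
    }
    if (tp + fp == 0) 0 else tp / (tp + fp)
  })
  mean(prec)
}

# random smooth test image (correlated noise), as PressureImage
randomSmoothImage <- function(n = 48, scale = 60) {
  g <- matrix(stats::rnorm((n %/% 4)^2), n %/% 4, n %/% 4)
  up <- plantarseg:::.bilinear(g, n, n)
  v <- round(127 + scale * up / max(abs(up)))
  PressureImage(matrix(as.integer(pmin(pmax(v, 0), 255)), n, n))
}

# random blob mask (union of a few ellipses) with holes filled, so the
# outer-border oracle is well defined
randomBlobMask <- function(n = 40, nblob = 2) {
  m <- matrix(FALSE, n, n)
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), n), n, n)
  for (k in seq_len(nblob)) {
    cx <- stats::runif(1, 8, n - 8); cy <- stats::runif(1, 8, n - 8)
    a <- stats::runif(1, 3, 7); b <- stats::runif(1, 3, 7)
    m <- m | ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  }
  BinaryMask(fillHoles(m))
}

# 4-connected flood fill from the border; unreached background is a hole
fillHoles <- function(fg) {
  n <- nrow(fg); nc <- ncol(fg)
  outside <- matrix(FALSE, n, nc)
  queue <- which(!fg & (row(fg) %in% c(1, n) | col(fg) %in% c(1, nc)))
  outside[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1) %% n + 1; cc <- (i - 1) %/% n + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1 || rr > n || c2 < 1 || c2 > nc) next
      j <- (c2 - 1) * n + rr
      if (!fg[j] && !outside[j]) { outside[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  fg | !outside
}

# deterministic little footprint image for backend comparisons
tinyFootprint <- function(seed = 5L, type = "normal") {
  generateFootprint(synthSpec(type, side = "left", imageSize = c(256L, 256L),
    footLength = 150L, seed = seed))
}
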