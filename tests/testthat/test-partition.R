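test_that("toe blobs are excluded by the area filter before partitioning", {
  m <- matrix(0L, 300, 200)
  m[81:280, 41:160] <- 255L # sole: 200x120 block, area >> 6000
  # five small toe blobs above, each far below the area threshold
  for (cx in seq(50, 150, by = 25)) m[61:70, cx:(cx + 9)] <- 255L
  cs <- traceContours(BinaryMask(m))
  expect_length(cs, 6)
  kept <- filterByArea(cs, 6000)
  expect_length(kept, 1)
  reg <- assignRegions(kept, 700) # bounding x = 40 < 350 -> left
  pts <- collectFootPoints(kept, reg, "left")
  expect_true(all(pts[, 2] >= 80)) # no toe pixels survive
  expect_error(collectFootPoints(kept, reg, "right"), "missing foot.*right")
})

test_that("separated forefoot and heel contours are united per side", {
  m <- matrix(0L, 400, 200)
  m[51:150, 41:160] <- 255L  # forefoot block
  m[231:330, 61:140] <- 255L # heel block (disconnected, high arch)
  cs <- filterByArea(traceContours(BinaryMask(m)), 6000)
  expect_length(cs, 2)
  reg <- assignRegions(cs, 700)
  pts <- collectFootPoints(cs, reg, "left")
  expect_setequal(unique(pts[, 2] < 200), c(TRUE, FALSE)) # both blocks present
})

test_that("foot length is the inclusive y extent", {
  pts <- cbind(x = rep(0, 100), y = 0:99)
  expect_equal(unname(footLength(pts)["length"]), 100)
  expect_equal(unname(footLength(cbind(5, 7))["length"]), 1)
  expect_equal(unname(footLength(cbind(x = 0, y = 120:419))["length"]), 300)
  expect_error(footLength(cbind(numeric(0), numeric(0))), "empty")
})

test_that("band lengths follow 30/30/40 with floor-and-remainder rounding", {
  expect_equal(unname(bandLengths(100)), c(30, 30, 40))
  expect_equal(unname(bandLengths(10)), c(3, 3, 4))
  expect_equal(unname(bandLengths(3)), c(0, 0, 3)) # degenerate, caught later
  expect_error(bandLengths(2), "degenerate")
  # conservation for every length 3..2000
  for (L in 3:2000) expect_equal(sum(bandLengths(L)), L)
})

test_that("the forefoot splits at the x midpoint with the shared column", {
  # full rectangle foot: x 0..10, y 0..99, left side
  pts <- as.matrix(expand.grid(x = 0:10, y = 0:99))
  part <- buildPartition(pts, "left")
  b <- partitionBoxes(part)
  outer <- b[b$label == "outerForefoot", ]
  inner <- b[b$label == "innerForefoot", ]
  expect_equal(outer$x, 0); expect_equal(outer$x + outer$w - 1, 5)
  expect_equal(inner$x, 5); expect_equal(inner$x + inner$w - 1, 10)
  arch <- b[b$label == "midfoot", ]
  heel <- b[b$label == "heel", ]
  expect_equal(c(arch$y, arch$y + arch$h), c(30, 60))
  expect_equal(c(heel$y, heel$y + heel$h), c(60, 100))
})

test_that("partition y-intervals tile the foot exactly", {
  set.seed(41)
  for (k in 1:20) {
    npt <- sample(50:200, 1)
    pts <- cbind(x = sample(0:80, npt, TRUE), y = sample(0:150, npt, TRUE))
    fl <- footLength(pts)
    part <- tryCatch(buildPartition(pts, "left"), error = function(e) NULL)
    if (is.null(part)) next
    b <- partitionBoxes(part)
    ys <- b[match(c("outerForefoot", "midfoot", "heel"), b$label), ]
    expect_equal(ys$y[1], unname(fl["yMin"]))
    expect_equal(ys$y[2], ys$y[1] + ys$h[1])
    expect_equal(ys$y[3], ys$y[2] + ys$h[2])
    expect_equal(ys$y[3] + ys$h[3], unname(fl["yMax"]) + 1)
  }
})

test_that("partitioning is translation- and mirror-equivariant", {
  set.seed(42)
  for (k in 1:50) {
    npt <- sample(60:150, 1)
    pts <- cbind(x = sample(10:60, npt, TRUE), y = sample(20:140, npt, TRUE))
    part <- tryCatch(buildPartition(pts, "left"), error = function(e) NULL)
    if (is.null(part)) next
    b <- partitionBoxes(part)
    # translation
    dx <- sample(-5:20, 1); dy <- sample(-10:15, 1)
    b2 <- partitionBoxes(buildPartition(cbind(pts[, 1] + dx, pts[, 2] + dy),
      "left"))
    expect_equal(b2$x, b$x + dx)
    expect_equal(b2$y, b$y + dy)
    expect_equal(b2$w, b$w); expect_equal(b2$h, b$h)
    # mirror across a vertical axis x -> W-1-x swaps side and outer/inner
    W <- 200
    bm <- partitionBoxes(buildPartition(cbind(W - 1 - pts[, 1], pts[, 2]),
      "right"))
    for (lab in regionLabels()) {
      a <- b[b$label == lab, ]
      mlab <- switch(lab, outerForefoot = "outerForefoot",
        innerForefoot = "innerForefoot", lab)
      m <- bm[bm$label == mlab, ]
      expect_equal(m$x, W - 1 - (a$x + a$w - 1)) # mirrored interval
      expect_equal(m$w, a$w)
      expect_equal(m$y, a$y); expect_equal(m$h, a$h)
    }
  }
})

test_that("incomplete feet raise errors naming the empty band", {
  pts <- as.matrix(expand.grid(x = 0:20, y = c(0:29, 61:99))) # no arch rows
  expect_error(buildPartition(pts, "left"), "arch")
  expect_error(buildPartition(as.matrix(expand.grid(x = 0:5, y = 0:2)),
    "left"), "degenerate")
})

test_that("arch index thirds and categories match the published bands", {
  mk <- function(nMid, nOut) {
    # nMid points in the middle third of y 0..99, nOut split at the ends
    rbind(cbind(0, rep(50, nMid)), cbind(0, rep(0, ceiling(nOut / 2))),
      cbind(0, rep(99, floor(nOut / 2))))
  }
  expect_equal(archIndex(mk(20, 80))$category, "high_arch") # ai = 0.20
  expect_equal(archIndex(mk(23, 77))$category, "normal")    # ai = 0.23
  expect_equal(archIndex(mk(26, 74))$category, "flat")      # ai = 0.26
  # solid rectangle: ai = 1/3 -> flat
  rect <- as.matrix(expand.grid(x = 0:9, y = 0:98))
  res <- archIndex(rect)
  expect_equal(res$ai, 1 / 3, tolerance = 1e-12)
  expect_equal(res$category, "flat")
  # quantization error at most 2/L for uniform rectangles
  for (L in c(10, 31, 50, 97, 200)) {
    r <- archIndex(as.matrix(expand.grid(x = 0:4, y = 0:(L - 1))))
    expect_lte(abs(r$ai - 1 / 3), 2 / L)
  }
  expect_error(archIndex(cbind(numeric(0), numeric(0))), "empty")
})
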