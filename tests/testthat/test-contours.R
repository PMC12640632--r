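test_that("border following enumerates exactly the boundary pixels", {
  expect_length(traceContours(BinaryMask(matrix(0L, 10, 10))), 0)

  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 255L # filled 10x10 square
  cs <- traceContours(BinaryMask(m))
  expect_length(cs, 1)
  pts <- contours(cs)[[1]]
  expect_equal(nrow(pts), 36) # 4*10 - 4 boundary lattice pixels, each once
  expect_setequal(paste(pts[, 1], pts[, 2]),
    paste(bruteBoundary(m)[, 1], bruteBoundary(m)[, 2]))
  # consecutive points are 8-adjacent, wrapping around
  d <- pts[c(2:36, 1), ] - pts
  expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))

  m2 <- matrix(0L, 20, 20); m2[2:5, 2:5] <- 255L; m2[10:18, 8:16] <- 255L
  expect_length(traceContours(BinaryMask(m2)), 2)
})

test_that("traced point sets match the brute-force boundary oracle on blobs", {
  set.seed(33)
  for (k in 1:50) {
    mask <- randomBlobMask(40, nblob = sample(1:3, 1))
    cs <- traceContours(mask)
    got <- unique(do.call(rbind, contours(cs)))
    want <- bruteBoundary(pixels(mask))
    expect_setequal(paste(got[, 1], got[, 2]),
      paste(want[, 1], want[, 2]))
  }
})

test_that("tracing is translation-equivariant under zero padding", {
  set.seed(34)
  mask <- randomBlobMask(30)
  cs <- traceContours(mask)
  padded <- matrix(0L, 32, 32)
  padded[2:31, 2:31] <- pixels(mask)
  cs2 <- traceContours(BinaryMask(padded))
  expect_equal(length(cs), length(cs2))
  for (i in seq_along(contours(cs)))
    expect_equal(contours(cs2)[[i]], contours(cs)[[i]] + 1L,
      ignore_attr = TRUE)
})

test_that("shoelace area matches closed forms and Pick's theorem", {
  expect_equal(shoelaceArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(shoelaceArea(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_equal(shoelaceArea(rbind(c(0, 0), c(4, 0))), 0) # n < 3
  set.seed(35)
  for (k in 1:100) {
    poly <- randomSimplePolygon()
    a <- shoelaceArea(poly)
    expect_equal(a, shoelaceArea(poly[rev(seq_len(nrow(poly))), ]))
    expect_equal(a, pickArea(poly)) # lattice-exact
    # rasterization count differs by at most ~half the perimeter
    peri <- sum(sqrt(rowSums((poly[c(2:nrow(poly), 1), ] - poly)^2)))
    inPx <- 0
    for (px in min(poly[, 1]):max(poly[, 1]))
      for (py in min(poly[, 2]):max(poly[, 2]))
        if (.onBoundary(px, py, poly[, 1], poly[, 2]) ||
            pointInPoly(px, py, poly[, 1], poly[, 2])) inPx <- inPx + 1
    expect_lte(abs(a - inPx), peri / 2 + 1)
  }
})

test_that("area filtering is strict, order-preserving and idempotent", {
  dummy <- lapply(c(5999, 6000, 6001, 12000), function(a)
    rbind(c(0, 0), c(a, 0), c(0, 2))) # triangle area = a
  cs <- new("ContourSet", contours = dummy,
    areas = vapply(dummy, shoelaceArea, numeric(1)))
  expect_equal(contourAreas(cs), c(5999, 6000, 6001, 12000))
  kept <- filterByArea(cs, 6000)
  expect_equal(contourAreas(kept), c(6001, 12000)) # strictly greater only
  expect_equal(contourAreas(filterByArea(kept, 6000)), contourAreas(kept))
  expect_length(filterByArea(new("ContourSet"), 6000), 0)
  expect_equal(contourAreas(filterByArea(cs, 0)), contourAreas(cs))
})

test_that("bounding boxes contain their contours and sides follow the rule", {
  set.seed(36)
  mask <- randomBlobMask(40, 2)
  cs <- traceContours(mask)
  reg <- assignRegions(cs, 40)
  for (i in seq_len(nrow(reg))) {
    p <- contours(cs)[[reg$contour[i]]]
    expect_true(all(p[, 1] >= reg$x[i] & p[, 1] < reg$x[i] + reg$w[i]))
    expect_true(all(p[, 2] >= reg$y[i] & p[, 2] < reg$y[i] + reg$h[i]))
  }
  # side rule: strict x < imgWidth/2
  mk <- function(x0) rbind(c(x0, 5), c(x0 + 3, 5), c(x0 + 3, 9), c(x0, 9))
  cs2 <- new("ContourSet", contours = list(mk(10), mk(350), mk(500)),
    areas = c(100, 100, 100))
  reg2 <- assignRegions(cs2, 700)
  expect_equal(reg2$side, c("left", "right", "right")) # 350 is not < 350
})
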