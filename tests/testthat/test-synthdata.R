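test_that("generation is deterministic under a fixed seed", {
  s1 <- generateFootprint(synthSpec("normal", seed = 9L))
  s2 <- generateFootprint(synthSpec("normal", seed = 9L))
  expect_identical(pixels(s1$image), pixels(s2$image))
  expect_identical(s1$gtBoxes, s2$gtBoxes)
  s3 <- generateFootprint(synthSpec("normal", seed = 10L))
  expect_false(identical(pixels(s1$image), pixels(s3$image)))
})

# contact fraction of the midfoot band, measured on the true geometry:
# sole pixels in the band relative to the band's bounding-box area
.midfootFraction <- function(smp, side = "left") {
  gt <- smp$gtBoxes
  arch <- gt[gt$label == "midfoot" & gt$side == side, ]
  band <- smp$gtMask[(arch$y:(arch$y + arch$h - 1)) + 1, , drop = FALSE]
  sum(band > 0) / (arch$h * arch$w)
}

test_that("midfoot contact matches the morphology definitions", {
  frN <- .midfootFraction(generateFootprint(synthSpec("normal",
    side = "left", seed = 61L)))
  expect_gte(frN, 0.4); expect_lte(frN, 0.6) # ~50 percent contact
  frL <- .midfootFraction(generateFootprint(synthSpec("low_arch",
    side = "left", seed = 61L)))
  frH <- .midfootFraction(generateFootprint(synthSpec("high_arch",
    side = "left", seed = 61L)))
  expect_lt(frH, frN) # minimal contact
  expect_gt(frL, frN) # near-complete contact
})

test_that("midfoot foreground area increases strictly with the contact dial", {
  px <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(cc) {
    smp <- generateFootprint(synthSpec("normal", side = "left",
      midfootContact = cc, seed = 77L))
    arch <- smp$gtBoxes[smp$gtBoxes$label == "midfoot", ]
    sum(smp$gtMask[(arch$y:(arch$y + arch$h - 1)) + 1, ] == 3)
  })
  expect_true(all(diff(px) > 0))
})

test_that("tilt morphologies alter toes and heel as defined", {
  nIn <- generateFootprint(synthSpec("inward_tilt", side = "left",
    seed = 62L))
  nOut <- generateFootprint(synthSpec("outward_tilt", side = "left",
    seed = 62L))
  nNorm <- generateFootprint(synthSpec("normal", side = "left", seed = 62L))
  # toe pixels: clearly loaded but outside the sole ground-truth mask
  toeArea <- function(s) sum(pixels(s$image) > 50 & s$gtMask == 0)
  # both tilt types register fewer toes than the full complement
  expect_lt(toeArea(nIn), toeArea(nNorm))
  expect_lt(toeArea(nOut), toeArea(nNorm))
  none <- generateFootprint(synthSpec("normal", side = "left",
    completeness = "missing_toes", seed = 62L))
  expect_lt(toeArea(none), toeArea(nOut))
})

test_that("ground-truth band boxes tile the true foot length", {
  for (ty in footTypes()) {
    smp <- generateFootprint(synthSpec(ty, seed = 63L))
    for (s in c("left", "right")) {
      b <- smp$gtBoxes[smp$gtBoxes$side == s, ]
      expect_equal(nrow(b), 4)
      ys <- b[match(c("outerForefoot", "midfoot", "heel"), b$label), ]
      expect_equal(ys$y[2], ys$y[1] + ys$h[1])
      expect_equal(ys$y[3], ys$y[2] + ys$h[2])
      L <- smp$meta$geometry[[s]]$footLength
      expect_equal(ys$h[1] + ys$h[2] + ys$h[3], L)
      expect_equal(unname(bandLengths(L)),
        c(ys$h[1], ys$h[2], ys$h[3]))
    }
  }
})

test_that("dataset apportionment follows the published composition", {
  m200 <- generateDataset(200, seed = 1)
  expect_equal(sum(m200$group == "normal"), 80)
  expect_equal(sum(m200$group == "abnormal"), 120)
  expect_equal(unname(table(m200$type)[footTypes()]),
    c(80, 30, 30, 30, 30), ignore_attr = TRUE)
  m10 <- generateDataset(10, seed = 1)
  expect_equal(sum(m10$group == "normal"), 4)
  expect_equal(sum(m10$group == "abnormal"), 6)
  expect_identical(generateDataset(10, seed = 5), generateDataset(10, seed = 5))
  expect_error(generateDataset(3, seed = 1), "at least 5")
})

test_that("written datasets round-trip through the image and gt readers", {
  dir <- tempfile("synthds")
  man <- generateDataset(5, seed = 8, outDir = dir,
    imageSize = c(256L, 256L))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (i in seq_len(nrow(man))) {
    smp <- manifestSample(man, i)
    img <- readPressureImage(man$file[i])
    expect_identical(pixels(img), pixels(smp$image))
    for (f in c(man$gtYolo[i], man$gtJson[i])) {
      back <- readGroundTruth(f, 256, 256)
      ord <- order(back$side, match(back$label, regionLabels()))
      ord0 <- order(smp$gtBoxes$side,
        match(smp$gtBoxes$label, regionLabels()))
      expect_equal(back[ord, ], smp$gtBoxes[ord0, ], ignore_attr = TRUE)
    }
  }
  unlink(dir, recursive = TRUE)
})

test_that("ground truth scores IoU 1 against itself end to end", {
  smp <- generateFootprint(synthSpec("normal", seed = 64L))
  gt <- smp$gtBoxes; gt$image <- "x"
  res <- averagePrecision(gt, gt)
  expect_true(all(res$perRegion$meanIoU == 1))
  expect_equal(res$map, 1)
})

test_that("a foot larger than its canvas is rejected", {
  expect_error(synthSpec("normal", imageSize = c(200L, 200L),
    footLength = 180L), "fit")
})
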