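test_that("rectangle IoU matches closed forms and the pixel-count oracle", {
  a <- pixelRect(0, 0, 10, 10)
  expect_equal(iouRect(a, a), 1)
  expect_equal(iouRect(a, pixelRect(20, 20, 5, 5)), 0)
  expect_equal(iouRect(a, pixelRect(5, 0, 10, 10)), 50 / 150)
  set.seed(51)
  for (k in 1:1000) {
    b1 <- pixelRect(sample(0:20, 1), sample(0:20, 1), sample(1:15, 1),
      sample(1:15, 1))
    b2 <- pixelRect(sample(0:20, 1), sample(0:20, 1), sample(1:15, 1),
      sample(1:15, 1))
    got <- iouRect(b1, b2)
    expect_equal(got, iouRect(b2, b1))
    expect_gte(got, 0); expect_lte(got, 1)
    expect_equal(got, bruteIoU(b1, b2))
  }
})

test_that("performance bands partition [0,1] with the published boundaries", {
  expect_equal(performanceBand(0.95), "excellent")
  expect_equal(performanceBand(0.90), "excellent")
  expect_equal(performanceBand(0.60), "good")
  expect_equal(performanceBand(0.59), "poor")
  expect_error(performanceBand(1.2), "out of")
  grid <- seq(0, 1, by = 0.001)
  bands <- performanceBand(grid)
  expect_true(all(bands %in% c("poor", "good", "excellent")))
  expect_equal(unname(table(bands)["poor"]), sum(grid < 0.6))
  expect_equal(unname(table(bands)["excellent"]), sum(grid >= 0.9))
})

.mkBoxes <- function(df) {
  # df: image, side, label, plus pred box width for IoU control
  gt <- data.frame(image = df$image, side = df$side, label = df$label,
    x = 0, y = 0, w = 10, h = 10, stringsAsFactors = FALSE)
  pred <- gt
  pred$w <- df$predW
  list(pred = pred, gt = gt)
}

test_that("average precision reduces to threshold-sweep precision", {
  imgs <- sprintf("i%02d", 1:10)
  exact <- .mkBoxes(data.frame(image = imgs, side = "left",
    label = "heel", predW = 10))
  apx <- averagePrecision(exact$pred, exact$gt)
  expect_equal(apx$perRegion$ap, 1)
  expect_equal(apx$map, 1)

  disjoint <- exact
  disjoint$pred$x <- 50
  expect_equal(averagePrecision(disjoint$pred, disjoint$gt)$perRegion$ap, 0)

  # widths 1..10 give IoUs 0.1..1.0 straddling every threshold
  mixed <- .mkBoxes(data.frame(image = imgs, side = "left", label = "heel",
    predW = 1:10))
  got <- averagePrecision(mixed$pred, mixed$gt)
  expect_equal(got$perRegion$ap,
    bruteAP(mixed$pred, mixed$gt, seq(0.5, 0.95, by = 0.05)))
  # per-threshold precision is monotone non-increasing in the threshold
  ap1 <- sapply(seq(0.5, 0.95, 0.05), function(t)
    averagePrecision(mixed$pred, mixed$gt, iouThresholds = t)$perRegion$ap)
  expect_true(all(diff(ap1) <= 0))
  # mAP is the mean of per-region APs to machine precision
  two <- rbind(
    cbind(mixed$pred, stringsAsFactors = FALSE),
    transform(mixed$pred, label = "midfoot", w = 8))
  twoGt <- rbind(mixed$gt, transform(mixed$gt, label = "midfoot"))
  res <- averagePrecision(two, twoGt)
  expect_equal(res$map, mean(res$perRegion$ap))
})

test_that("predictions without ground truth count as false positives", {
  p <- .mkBoxes(data.frame(image = "a", side = "left", label = "heel",
    predW = 10))
  spur <- rbind(p$pred,
    data.frame(image = "a", side = "left", label = "midfoot",
      x = 0, y = 0, w = 10, h = 10))
  res <- averagePrecision(spur, p$gt)
  expect_equal(res$perRegion$ap[res$perRegion$label == "midfoot"], 0)
  expect_equal(res$perRegion$ap[res$perRegion$label == "heel"], 1)
})

test_that("the grouped report averages in two steps, not pooled", {
  # one normal image at IoU 0.9, one abnormal at IoU 0.8
  gt <- data.frame(image = c("n1", "a1"), side = "left", label = "heel",
    x = 0, y = 0, w = 10, h = 10, stringsAsFactors = FALSE)
  pred <- gt; pred$w <- c(9, 8)
  groups <- data.frame(image = c("n1", "a1"), group = c("normal", "abnormal"))
  rep <- groupedReport(pred, gt, groups)
  expect_equal(rep@perRegion$meanIoU, 0.85)
  expect_equal(rep@perRegion$iou_normal, 0.9)
  expect_equal(rep@perRegion$iou_abnormal, 0.8)

  # identical groups: two-step equals either group
  pred$w <- c(9, 9)
  expect_equal(groupedReport(pred, gt, groups)@perRegion$meanIoU, 0.9)

  # 80 normal / 120 abnormal: two-step differs from the pooled mean
  set.seed(52)
  imgs <- sprintf("s%03d", 1:200)
  grp <- data.frame(image = imgs,
    group = rep(c("normal", "abnormal"), c(80, 120)))
  gt2 <- data.frame(image = imgs, side = "left", label = "heel",
    x = 0, y = 0, w = 10, h = 10, stringsAsFactors = FALSE)
  pred2 <- gt2
  pred2$w <- c(sample(8:10, 80, TRUE), sample(4:7, 120, TRUE))
  rep2 <- groupedReport(pred2, gt2, grp)
  iouOf <- function(w) w / 10
  mN <- mean(iouOf(pred2$w[1:80])); mA <- mean(iouOf(pred2$w[81:200]))
  expect_equal(rep2@perRegion$meanIoU, (mN + mA) / 2)
  expect_equal(rep2@perRegion$iouPooled, mean(iouOf(pred2$w)))
  expect_false(isTRUE(all.equal(rep2@perRegion$meanIoU,
    rep2@perRegion$iouPooled)))

  # a missing group warns and falls back to the present group
  gOnly <- data.frame(image = c("n1", "a1"), group = "normal")
  expect_warning(rep3 <- groupedReport(pred[1, ], gt, gOnly), "absent")
  expect_equal(rep3@perRegion$iou_normal, rep3@perRegion$meanIoU)
})

test_that("missing predictions are reported as failures with IoU zero", {
  gt <- data.frame(image = c("n1", "n1"), side = c("left", "right"),
    label = "heel", x = 0, y = 0, w = 10, h = 10, stringsAsFactors = FALSE)
  pred <- gt[1, ]
  groups <- data.frame(image = "n1", group = "normal")
  expect_warning(rep <- groupedReport(pred, gt, groups), "absent")
  expect_equal(nrow(rep@failures), 1)
  expect_equal(rep@failures$side, "right")
  pr <- rep@perRegion
  expect_equal(pr$meanIoU[pr$side == "right"], 0)
})
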