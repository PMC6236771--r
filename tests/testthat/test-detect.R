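# Circular Hough transform detection and nonmaximum suppression.

test_that("a rendered disk is recovered at its centre and radius", {
  fx <- renderDiskImage(160, c(60, 80), 10, seed = 2)
  cands <- chtDetect(fx$img, fx$lung, band = c(3, 12), spacingMM = 0.7)
  expect_gt(nrow(cands), 0)
  top <- cands[1, ]
  expect_lte(sqrt((top$row - 60)^2 + (top$col - 80)^2), 2)
  expect_lte(abs(top$radius_px - 10), 1)
  expect_equal(top$radius_mm, top$radius_px * 0.7)
  # determinism
  expect_identical(cands, chtDetect(fx$img, fx$lung, c(3, 12),
                                    spacingMM = 0.7))
})

test_that("two disjoint disks are both recovered after suppression", {
  fx <- renderDiskImage(200, c(60, 60), 6, seed = 3)
  dd <- sqrt(outer((1:200 - 140)^2, (1:200 - 140)^2, "+"))
  fx$img[dd <= 14] <- 0.7
  cands <- detectAllBands(fx$img, fx$lung, spacingMM = 0.7,
                          bands = list(small = c(3, 12), medium = c(8, 20)))
  d1 <- min(sqrt((cands$row - 60)^2 + (cands$col - 60)^2))
  d2 <- min(sqrt((cands$row - 140)^2 + (cands$col - 140)^2))
  expect_lte(d1, 2)
  expect_lte(d2, 2)
})

test_that("empty masks yield empty candidate lists", {
  fx <- renderDiskImage(100, c(50, 50), 8, seed = 4)
  none <- chtDetect(fx$img, matrix(0L, 100, 100), c(3, 12), spacingMM = 0.7)
  expect_equal(nrow(none), 0)
  blank <- detectAllBands(matrix(0.2, 100, 100),
                          renderDiskImage(100, c(50, 50), 8)$lung,
                          spacingMM = 0.7)
  expect_equal(nrow(blank), 0)
})

test_that("every returned centre lies inside the lung mask", {
  ph <- phantomSlice(phantomSpec(), seed = 104, diametersMM = c(10, 22),
                     labels = c("benign", "malign"))
  enh <- enhance(ph$slice)
  lv <- luvemExtract(enh)
  cands <- detectAllBands(lv$lungImage, lv$mask)
  expect_true(all(lv$mask[cbind(cands$row, cands$col)] == 1L))
})

test_that("raising the score threshold never increases the candidate count", {
  fx <- renderDiskImage(160, c(80, 80), 9, noiseSD = 0.03, seed = 5)
  ns <- vapply(c(0.1, 0.3, 0.5, 0.8), function(th) {
    nrow(chtDetect(fx$img, fx$lung, c(3, 12),
                   chtParams(scoreThreshold = th), spacingMM = 0.7))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("greedy suppression keeps the dominant candidate per site", {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      radius_px = numeric(0), score = numeric(0))
  expect_equal(nrow(nonmaxSuppress(empty)), 0)
  dup <- data.frame(row = c(10, 10), col = c(10, 10), radius_px = c(5, 5),
                    score = c(5, 3))
  kept <- nonmaxSuppress(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 5)
  # three collinear candidates 10 px apart, suppression distance 15
  tri <- data.frame(row = c(10, 20, 30), col = rep(10, 3),
                    radius_px = rep(20, 3), score = c(3, 2, 1))
  kept2 <- nonmaxSuppress(tri, minCenterDistPx = 15)
  expect_equal(kept2$score, c(3, 1))
})

test_that("radius bands convert mm to pixels rounding outward", {
  expect_equal(lucad:::.bandRadiiPx(c(3, 12), 0.7), 4:18)
  expect_equal(lucad:::.bandRadiiPx(c(15, 45), 0.7), 21:65)
  # coarse spacing still leaves at least one radius
  expect_equal(lucad:::.bandRadiiPx(c(3, 12), 10), 1:2)
  expect_equal(names(radiusBands()), c("small", "medium", "large"))
})
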