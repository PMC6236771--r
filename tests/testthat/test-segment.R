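# ROI extraction and SOM segmentation.

test_that("ROI geometry follows the side formula with clipping and clamping", {
  sl <- CTSlice(matrix(runif(100 * 100), 100), 0.7)
  roi <- extractROI(sl, data.frame(row = 50, col = 50, radius_px = 10))
  expect_equal(dim(roi$pixels), c(31L, 31L))   # 2 * ceil(1.5 * 10) + 1
  expect_equal(unname(roi$center), c(16L, 16L))
  # near a corner the window shifts to fit but still contains the centre
  roi2 <- extractROI(sl, data.frame(row = 2, col = 3, radius_px = 10))
  expect_equal(unname(roi2$origin), c(1L, 1L))
  expect_equal(unname(roi2$center), c(2L, 3L))
  # minimum side clamp
  roi3 <- extractROI(sl, data.frame(row = 50, col = 50, radius_px = 2))
  expect_equal(nrow(roi3$pixels), 9L)
  expect_error(extractROI(sl, data.frame(row = 50, col = 50, radius_px = 60)),
               "too large")
  expect_error(extractROI(sl, data.frame(row = 500, col = 50, radius_px = 5)),
               "outside")
})

test_that("SOM training converges on two separated clusters and is seeded", {
  set.seed(42)
  samples <- cbind(c(rep(0.1, 60), rep(0.9, 60)) + rnorm(120, 0, 0.005))
  cfg <- somConfig(nNodes = 2, seed = 17)
  m <- somTrain(samples, cfg)
  expect_equal(sort(m@weights[, 1]), c(0.1, 0.9), tolerance = 0.05)
  # identical seed, identical model
  m2 <- somTrain(samples, cfg)
  expect_identical(m@weights, m2@weights)
  # all-identical samples collapse every prototype onto the sample
  same <- matrix(0.37, 30, 2)
  ms <- somTrain(same, somConfig(seed = 3))
  expect_true(all(abs(ms@weights - 0.37) < 1e-12))
  expect_error(somTrain(matrix(1:3, 3, 1), somConfig(nNodes = 4, seed = 1)),
               "at least nNodes")
  expect_error(somConfig(nNodes = 4), "seed")
})

test_that("SOM segmentation isolates a bright disk with high overlap", {
  for (k in 1:5) {
    fx <- diskROI(radiusPx = 5 + 2 * k, contrast = 3 + k, seed = 10 + k)
    model <- somTrain(lucad:::somPixelFeatures(fx$roi$pixels),
                      somConfig(seed = 20 + k))
    seg <- somSegment(fx$roi, model)
    expect_gte(dice(seg$mask, fx$truth), 0.9)
    # exactly one connected component
    lab <- lucad:::cpp_label(seg$mask, 8L)
    expect_equal(max(lab), 1L)
  }
})

test_that("segmentation is deterministic and flags degenerate ROIs", {
  fx <- diskROI(radiusPx = 8, seed = 30)
  s1 <- segmentCandidate(fx$roi$pixels, fx$roi$candidate, somConfig(seed = 5))
  s2 <- segmentCandidate(fx$roi$pixels, fx$roi$candidate, somConfig(seed = 5))
  expect_identical(s1$mask, s2$mask)
  # uniform ROI: degenerate, warned, empty-or-full
  uni <- structure(list(pixels = matrix(0.5, 21, 21),
                        origin = c(row = 1L, col = 1L),
                        center = c(row = 11L, col = 11L),
                        candidate = data.frame(row = 11, col = 11,
                                               radius_px = 5)),
                   class = "noduleROI")
  model <- somTrain(lucad:::somPixelFeatures(uni$pixels), somConfig(seed = 1))
  expect_warning(segU <- somSegment(uni, model), "degenerate")
  expect_true(sum(segU$mask) %in% c(0L, 21L * 21L))
  expect_true(segU$degenerate)
})
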