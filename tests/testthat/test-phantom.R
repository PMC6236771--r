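# Synthetic chest phantom generator.

test_that("slices are bit-identical under a fixed seed", {
  spec <- phantomSpec()
  p1 <- phantomSlice(spec, seed = 5, diametersMM = c(8, 20),
                     labels = c("benign", "malign"))
  p2 <- phantomSlice(spec, seed = 5, diametersMM = c(8, 20),
                     labels = c("benign", "malign"))
  expect_identical(pixels(p1$slice), pixels(p2$slice))
  expect_identical(p1$lungMask, p2$lungMask)
  expect_identical(p1$nodules[[2]]$mask, p2$nodules[[2]]$mask)
  # a different seed changes the slice
  p3 <- phantomSlice(spec, seed = 6, diametersMM = c(8, 20),
                     labels = c("benign", "malign"))
  expect_false(identical(pixels(p1$slice), pixels(p3$slice)))
})

test_that("nodule truth masks are disjoint subsets of the lung fields", {
  ph <- phantomSlice(phantomSpec(), seed = 7, diametersMM = c(6, 12, 25),
                     labels = c("benign", "malign", "malign"))
  overlap <- matrix(0L, 512, 512)
  for (nd in ph$nodules) {
    expect_true(all(ph$lungMask[nd$mask == 1L] == 1L))
    expect_equal(sum(overlap & nd$mask), 0)
    overlap <- overlap | nd$mask
    expect_gt(sum(nd$mask), 0)
  }
})

test_that("malign interiors carry more intensity variance than benign", {
  vb <- vm <- c()
  for (sd in 1:10) {
    ph <- phantomSlice(phantomSpec(), seed = 400 + sd,
                       diametersMM = c(15, 15),
                       labels = c("benign", "malign"))
    px <- pixels(ph$slice)
    vb <- c(vb, var(px[ph$nodules[[1]]$mask == 1L]))
    vm <- c(vm, var(px[ph$nodules[[2]]$mask == 1L]))
  }
  expect_gt(mean(vm), mean(vb))
})

test_that("the dataset generator honours counts, bands and determinism", {
  d1 <- phantomDataset(nBenign = 6L, nMalign = 6L, sizeBins = c(4L, 4L, 4L),
                       seed = 31, keepImages = FALSE)
  expect_equal(nrow(d1$manifest), 12)
  expect_equal(sum(d1$manifest$label == "benign"), 6)
  expect_equal(unname(table(d1$manifest$band)[c("<10", "10-20", ">20")]),
               c(4L, 4L, 4L), ignore_attr = TRUE)
  expect_true(all(d1$manifest$diameter_mm >= 3 &
                    d1$manifest$diameter_mm <= 65))
  expect_true(all(d1$manifest$diameter_mm[d1$manifest$band == "<10"] < 10))
  expect_true(all(d1$manifest$diameter_mm[d1$manifest$band == ">20"] > 20))
  d2 <- phantomDataset(nBenign = 6L, nMalign = 6L, sizeBins = c(4L, 4L, 4L),
                       seed = 31, keepImages = FALSE)
  expect_identical(d1$manifest, d2$manifest)
  expect_error(phantomDataset(5, 5, sizeBins = c(4, 4, 4), seed = 1),
               "sum")
})

test_that("dataset files round-trip through a run directory", {
  dir <- file.path(tempdir(), "phantom_ds")
  d <- phantomDataset(nBenign = 2L, nMalign = 2L, sizeBins = c(2L, 1L, 1L),
                      seed = 12, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  mf <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 4)
  sid <- mf$slice_id[1]
  expect_true(file.exists(file.path(dir, paste0(sid, ".png"))))
  lung <- readMask(file.path(dir, paste0(sid, "_lung.png")))
  expect_equal(dim(lung), c(512L, 512L))
  unlink(dir, recursive = TRUE)
})

test_that("impossible placements fail with a helpful error", {
  expect_error(
    phantomSlice(phantomSpec(), seed = 9, diametersMM = rep(65, 4),
                 labels = rep("malign", 4)),
    "fewer or smaller")
  expect_error(phantomSpec(sizeRangeMM = c(2, 70)), "3, 65")
})
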