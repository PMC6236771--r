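# Enhancement chain: median, Laplacian sharpening, histogram equalization.

test_that("median denoising removes isolated outliers and keeps constants", {
  const <- matrix(0.4, 16, 16)
  expect_equal(medianDenoise(const, 3), const, tolerance = 1e-4)
  spike <- matrix(0, 15, 15); spike[8, 8] <- 1
  expect_equal(max(medianDenoise(spike, 3)), 0, tolerance = 1e-4)
  m <- matrix(1:9 / 10, 3, 3, byrow = TRUE)
  expect_equal(medianDenoise(m, 3)[2, 2], 0.5, tolerance = 1e-3)
  expect_error(medianDenoise(const, 4), "odd")
  expect_error(medianDenoise(const, 1), "odd")
})

test_that("Laplacian sharpening matches a hand convolution with reflect padding", {
  const <- matrix(0.3, 10, 10)
  expect_equal(laplacianSharpen(const, 0.7), const)
  x <- matrix(runif(16, 0.2, 0.8), 4, 4)
  expect_identical(laplacianSharpen(x, 0), x)
  # independent oracle: explicit loop convolution with reflected borders
  w <- 0.5
  refl <- function(i, n) { if (i < 1) 2 - i else if (i > n) 2 * n - i else i }
  expected <- x
  for (i in 1:4) for (j in 1:4) {
    lap <- x[refl(i - 1, 4), j] + x[refl(i + 1, 4), j] +
           x[i, refl(j - 1, 4)] + x[i, refl(j + 1, 4)] - 4 * x[i, j]
    expected[i, j] <- min(max(x[i, j] - w * lap, 0), 1)
  }
  expect_equal(laplacianSharpen(x, w), expected)
  # step edge: overshoot near the edge is clipped into [0, 1]
  step <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  out <- laplacianSharpen(step, 0.5)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(laplacianSharpen(x, -1), ">= 0")
})

test_that("histogram equalization follows the binned CDF map", {
  two <- matrix(c(rep(0.2, 128), rep(0.8, 128)), 16)
  out <- histEqualize(two, 256)
  expect_equal(sort(unique(as.vector(out))), c(0.5, 1.0))
  const <- matrix(0.3, 16, 16)
  outc <- histEqualize(const, 256)
  expect_equal(length(unique(as.vector(outc))), 1L)
  # monotone nondecreasing in input intensity
  set.seed(5)
  x <- matrix(runif(400), 20)
  y <- histEqualize(x, 64)
  o <- order(as.vector(x))
  expect_true(all(diff(as.vector(y)[o]) >= -1e-12))
  # an already-uniform ramp maps to itself within one bin width
  ramp <- matrix(seq(0, 1 - 1e-9, length.out = 1024), 32)
  expect_lt(max(abs(histEqualize(ramp, 256) - ramp)), 1 / 256 + 1e-9)
})

test_that("the enhancement chain composes median, sharpen, equalize", {
  const <- matrix(0.6, 33, 33)
  out <- enhance(const, enhanceConfig())
  expect_equal(length(unique(as.vector(out))), 1L)
  # weight 0 equals median followed by equalization
  set.seed(7)
  x <- matrix(runif(33 * 33), 33)
  cfg <- enhanceConfig(medianKernel = 3, sharpenWeight = 0, equalizeBins = 256)
  expect_equal(enhance(x, cfg), histEqualize(medianDenoise(x, 3), 256))
  # output histogram is closer to uniform than the input's
  set.seed(8)
  bimodal <- matrix(c(rnorm(600, 0.25, 0.03), rnorm(489, 0.7, 0.03)), 33)
  bimodal <- pmin(pmax(bimodal, 0), 1)
  chi2 <- function(m) {
    h <- tabulate(pmin(floor(m * 32) + 1, 32), 32)
    e <- length(m) / 32
    sum((h - e)^2 / e)
  }
  expect_lt(chi2(enhance(bimodal, enhanceConfig())), chi2(bimodal))
  expect_true(all(pixels(enhance(CTSlice(pmin(pmax(bimodal, 0), 1)))) >= 0))
})
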