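# Probabilistic neural network classifier.

test_that("fitting stores patterns verbatim and validates inputs", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c("benign", "malign"), 5)
  m <- pnnFit(X, y, sigma = 1)
  expect_equal(nrow(m@patterns), 10)
  expect_identical(m@patterns, X)
  expect_identical(m, pnnFit(X, y, sigma = 1))
  expect_error(pnnFit(X, y, sigma = 0), "positive")
  expect_error(pnnFit(X, rep("malign", 10), sigma = 1), "both classes")
  expect_error(pnnFit(X, c(rep("benign", 9), "weird"), sigma = 1), "unknown")
})

test_that("the delta-kernel limit returns the nearest pattern's label", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  y <- c("benign", "benign", "malign")
  m <- pnnFit(X, y, sigma = 1e-3)
  expect_equal(as.character(pnnPredict(m, X[3, ])$label), "malign")
  expect_equal(as.character(pnnPredict(m, X[1, ])$label), "benign")
})

test_that("posteriors normalize and exact ties resolve to benign", {
  m <- pnnFit(matrix(c(-1, 1), 2, 1), c("benign", "malign"), sigma = 1)
  p <- pnnPredict(m, matrix(0, 1, 1))
  expect_equal(p$posterior_benign, 0.5)
  expect_equal(p$posterior_malign, 0.5)
  expect_equal(as.character(p$label), "benign")
  set.seed(2)
  q <- pnnPredict(m, matrix(rnorm(20), 20, 1))
  expect_equal(q$posterior_benign + q$posterior_malign, rep(1, 20))
  expect_error(pnnPredict(m, matrix(0, 1, 3)), "width")
})

test_that("separable Gaussian blobs classify with high held-out accuracy", {
  tr <- gaussianBlobs(100, d = 5, sep = 4, seed = 3)
  te <- gaussianBlobs(100, d = 5, sep = 4, seed = 4)
  m <- pnnFit(tr$X, tr$y, sigma = 1)
  pred <- pnnPredict(m, te$X)
  expect_gte(mean(as.character(pred$label) == te$y), 0.95)
})

test_that("predictions are scale-equivariant in (patterns, query, sigma)", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("benign", "malign"), 10)
  q <- matrix(rnorm(10), 5, 2)
  p1 <- pnnPredict(pnnFit(X, y, sigma = 0.8), q)
  k <- 3.7
  p2 <- pnnPredict(pnnFit(k * X, y, sigma = k * 0.8), k * q)
  expect_equal(p1$posterior_malign, p2$posterior_malign, tolerance = 1e-12)
})

test_that("the wide-kernel limit returns the class priors", {
  set.seed(6)
  X <- matrix(rnorm(100), 50, 2)
  y <- c(rep("benign", 30), rep("malign", 20))
  pProp <- pnnPredict(pnnFit(X, y, sigma = 1e5, priors = "proportional"),
                      matrix(0, 1, 2))
  expect_equal(pProp$posterior_benign, 0.6, tolerance = 1e-3)
  pUnif <- pnnPredict(pnnFit(X, y, sigma = 1e5, priors = "uniform"),
                      matrix(0, 1, 2))
  expect_equal(pUnif$posterior_benign, 0.5, tolerance = 1e-3)
})

test_that("sigma selection is deterministic and picks a sensible spread", {
  tr <- gaussianBlobs(40, d = 3, sep = 3, seed = 7)
  s1 <- pnnSigmaSelect(tr$X, tr$y)
  s2 <- pnnSigmaSelect(tr$X, tr$y)
  expect_identical(s1$sigma, s2$sigma)
  expect_gte(max(s1$accuracy), 0.9)
})
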