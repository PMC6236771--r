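# Confusion matrices, performance criteria, ROC/AUC, LOOCV, size bands.

test_that("confusion counts follow the malign-positive convention", {
  cm <- confusion(c("malign", "malign", "malign", "benign", "benign"),
                  c("malign", "malign", "malign", "benign", "benign"))
  expect_equal(c(cm@TP, cm@FP, cm@FN, cm@TN), c(3L, 0L, 0L, 2L))
  cm2 <- confusion(c("malign", "benign"), c("malign", "malign"))
  expect_equal(c(cm2@TP, cm2@FP, cm2@FN, cm2@TN), c(1L, 1L, 0L, 0L))
  cm3 <- confusion(c("malign", "malign", "benign", "benign"),
                   c("malign", "benign", "malign", "benign"))
  expect_equal(c(cm3@TP, cm3@FP, cm3@FN, cm3@TN), c(1L, 1L, 1L, 1L))
  expect_error(confusion("malign", "positive"), "unknown")
  expect_error(confusion(c("malign", "benign"), "malign"), "equal length")
})

test_that("metrics handle perfect, undefined and empty cases", {
  v <- formatMetrics(performanceMetrics(ConfusionMatrix(1, 0, 0, 1)))
  expect_equal(unname(v), c(100, 100, 100, 100, 100, 1))
  # nothing predicted malign: PDV undefined, reported NA (never 0 or 100)
  r <- performanceMetrics(ConfusionMatrix(0, 0, 5, 5))
  expect_true(is.na(r$PDV))
  expect_equal(r$Sen, 0)
  expect_error(performanceMetrics(ConfusionMatrix(0, 0, 0, 0)), "empty")
})

# Recomputing published-style tables exposes four cells where the source
# tables' own rounding is internally inconsistent; exact recomputation gives
# (not asserted against the printed values): overall Sen 97.41 (printed
# 97.42), overall Spc 94.23 (94.24), small-band Spc 94.44 (94.45),
# large-band NDV 83.33 (83.34).
test_that("exact recomputation of the errata cells is self-consistent", {
  overall <- performanceMetrics(ConfusionMatrix(113, 6, 3, 98))
  expect_equal(roundHalfUp(overall$Sen, 2), 97.41)
  expect_equal(roundHalfUp(overall$Spc, 2), 94.23)
  small <- performanceMetrics(ConfusionMatrix(3, 4, 0, 68))
  expect_equal(roundHalfUp(small$Spc, 2), 94.44)
  large <- performanceMetrics(ConfusionMatrix(67, 1, 2, 10))
  expect_equal(roundHalfUp(large$NDV, 2), 83.33)
})

test_that("AUC equals the Mann-Whitney statistic and its invariances", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1),
                      c("malign", "malign", "benign", "benign"))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6),
                      rep(c("malign", "benign"), 3))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3),
                      c("malign", "benign", "malign", "benign"))$auc, 0.75)
  # strictly monotone transforms leave the AUC unchanged
  set.seed(8)
  s <- runif(40); y <- sample(c("benign", "malign"), 40, replace = TRUE,
                              prob = c(0.4, 0.6))
  a1 <- rocAuc(s, y)$auc
  expect_equal(rocAuc(qlogis(s * 0.98 + 0.01), y)$auc, a1)
  expect_error(rocAuc(s, rep("malign", 40)), "both classes")
})

test_that("leave-one-out recovers separable data and logs every fold", {
  bl <- gaussianBlobs(20, d = 6, sep = 4, seed = 9, allDims = TRUE)
  colnames(bl$X) <- paste0("f", 1:6)
  res <- loocv(bl$X, bl$y)
  expect_equal(nrow(res$log), 40)
  expect_gte(res$report$Acc, 95)
  expect_gte(res$auc, 0.95)
  # per-fold metadata is recorded
  expect_true(all(res$log$n_components >= 1))
  expect_true(all(res$log$sigma > 0))
})

test_that("conflicting duplicate rows cap accuracy at chance", {
  set.seed(10)
  base <- matrix(rnorm(60), 20, 3)
  X <- rbind(base, base)
  y <- c(rep("benign", 20), rep("malign", 20))
  res <- loocv(X, y)
  expect_lte(res$report$Acc, 55)
})

test_that("size bands partition cases and sum to the overall matrix", {
  set.seed(11)
  n <- 60
  y <- sample(c("benign", "malign"), n, replace = TRUE)
  p <- ifelse(runif(n) < 0.8, y, ifelse(y == "benign", "malign", "benign"))
  sz <- runif(n, 3, 40)
  rep_ <- sizeStratifiedReport(y, p, sz)
  ov <- rep_[rep_$band == "overall", ]
  bands <- rep_[rep_$band != "overall", ]
  expect_equal(sum(bands$n), ov$n)
  for (col in c("TP", "FP", "FN", "TN"))
    expect_equal(sum(bands[[col]]), ov[[col]])
  # boundary convention: 10 and 20 fall in the middle band
  r2 <- sizeStratifiedReport(c("malign", "malign"), c("malign", "malign"),
                             c(10, 20))
  expect_equal(r2$band[1], "10-20")
  expect_equal(r2$n[1], 2)
  # an empty band is omitted with a message
  expect_message(
    r3 <- sizeStratifiedReport(c("malign", "benign"), c("malign", "benign"),
                               c(5, 7)),
    "empty")
  expect_false("10-20" %in% r3$band)
})
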