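# The 123-feature vector: first-order statistics, shape, co-occurrence
# texture, wavelet energies.

test_that("feature names are 123, unique and stable", {
  fn <- featureNames()
  expect_length(fn, 123)
  expect_false(any(duplicated(fn)))
  expect_equal(sum(startsWith(fn, "ssf_")), 6)
  expect_equal(sum(startsWith(fn, "sbf_")), 16)
  expect_equal(sum(startsWith(fn, "gtf_")), 88)
  expect_equal(sum(startsWith(fn, "tef_")), 13)
})

test_that("first-order statistics match closed forms", {
  s <- ssfFeatures(rep(c(0, 1), 50))
  expect_equal(unname(s[c("ssf_mean", "ssf_variance", "ssf_entropy",
                          "ssf_skewness")]),
               c(0.5, 0.25, 1, 0))
  # symmetric three-point sample: zero skewness
  expect_equal(unname(ssfFeatures(rep(c(0.2, 0.5, 0.8), 10))["ssf_skewness"]),
               0)
  # zero-variance conventions
  cst <- ssfFeatures(rep(0.4, 10))
  expect_equal(unname(cst[c("ssf_sd", "ssf_variance", "ssf_entropy",
                            "ssf_skewness", "ssf_kurtosis")]),
               c(0, 0, 0, 0, 0))
  expect_error(ssfFeatures(0.5), "at least 2")
})

test_that("shape features match analytic values for disks and squares", {
  dk <- diskMask(69, c(35, 35), 30)
  sb <- sbfFeatures(dk)
  expect_gt(sb[["sbf_circularity"]], 0.95)
  expect_lt(sb[["sbf_circularity"]], 1.05)
  expect_lte(sb[["sbf_eccentricity"]], 0.15)
  expect_gte(sb[["sbf_solidity"]], 0.98)
  expect_equal(sb[["sbf_equiv_diameter"]], sqrt(4 * sum(dk) / pi))
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  s2 <- sbfFeatures(sq)
  expect_equal(s2[["sbf_area"]], 100)
  expect_equal(s2[["sbf_extent"]], 1)
  expect_equal(s2[["sbf_aspect_ratio"]], 1)
  expect_error(sbfFeatures(matrix(0L, 5, 5)), "empty")
})

test_that("spiculated masks score as more irregular than equal-area disks", {
  star <- starMaskFixture(81, c(41, 41), 20, amplitude = 0.35,
                          harmonics = 5, seed = 9)
  dk <- diskMask(81, c(41, 41), sqrt(sum(star) / pi))
  fs <- sbfFeatures(star); fd <- sbfFeatures(dk)
  expect_gt(fs[["sbf_radial_sd"]], fd[["sbf_radial_sd"]])
  expect_lt(fs[["sbf_circularity"]], fd[["sbf_circularity"]])
})

test_that("doubling a disk radius scales area ~4x and perimeter ~2x", {
  f1 <- sbfFeatures(diskMask(41, c(21, 21), 15))
  f2 <- sbfFeatures(diskMask(81, c(41, 41), 30))
  expect_equal(f2[["sbf_area"]] / f1[["sbf_area"]], 4, tolerance = 0.05)
  expect_equal(f2[["sbf_perimeter"]] / f1[["sbf_perimeter"]], 2,
               tolerance = 0.05)
})

test_that("the co-occurrence matrix matches hand-counted pairs", {
  m <- matrix(c(0, 1, 0, 1), 2, 2)  # rows (0,0) and (1,1)
  G <- glcmMatrix(m, glcmConfig(distance = 1, levels = 2), angle = 0)
  expect_equal(G, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  cst <- glcmMatrix(matrix(0.4, 6, 6), glcmConfig(levels = 8), angle = 0)
  expect_equal(sum(cst > 0), 1L)
  expect_equal(max(cst), 1)
  set.seed(2)
  r <- matrix(runif(100), 10)
  for (a in c(0, 45, 90, 135))
    expect_equal(sum(glcmMatrix(r, glcmConfig(), a)), 1)
  expect_error(glcmMatrix(matrix(0.5, 1, 2), glcmConfig(distance = 5), 0),
               "smaller than the displacement")
})

test_that("texture descriptors agree with the brute-force oracle", {
  # 2-level toy: contrast 0, ASM 0.5, correlation 1
  m <- matrix(c(0, 1, 0, 1), 2, 2)
  f <- lucad:::glcmFeatures(glcmMatrix(m, glcmConfig(distance = 1, levels = 2),
                                       0))
  expect_equal(unname(f[c("contrast", "asm", "correlation")]), c(0, 0.5, 1))
  # random 4x4 toy: package GLCM equals explicit pair counting at all angles
  set.seed(13)
  toy <- matrix(runif(16), 4)
  for (a in c(0, 45, 90, 135)) {
    expect_equal(glcmMatrix(toy, glcmConfig(distance = 1, levels = 4), a),
                 bruteGLCM(toy, 4, 1, a))
  }
  # constant ROI: per-angle degenerate descriptor values
  g <- gtfFeatures(matrix(0.7, 8, 8), glcmConfig())
  expect_length(g, 88)
  for (a in c(0, 45, 90, 135)) {
    expect_equal(g[[paste0("gtf_a", a, "_contrast")]], 0)
    expect_equal(g[[paste0("gtf_a", a, "_asm")]], 1)
    expect_equal(g[[paste0("gtf_a", a, "_homogeneity")]], 1)
    expect_equal(g[[paste0("gtf_a", a, "_entropy")]], 0)
  }
})

test_that("rotating an ROI by 90 degrees permutes the angle blocks", {
  set.seed(21)
  roi <- matrix(runif(144), 12)
  rot <- t(roi)[ncol(roi):1, ]   # 90-degree raster rotation
  g0 <- gtfFeatures(roi); g90 <- gtfFeatures(rot)
  strip <- function(v, a) {
    out <- v[startsWith(names(v), paste0("gtf_a", a, "_"))]
    names(out) <- sub("^gtf_a[0-9]+_", "", names(out))
    out
  }
  expect_equal(strip(g90, 90), strip(g0, 0), tolerance = 1e-12)
  expect_equal(strip(g90, 0), strip(g0, 90), tolerance = 1e-12)
  expect_equal(strip(g90, 135), strip(g0, 45), tolerance = 1e-12)
  expect_equal(strip(g90, 45), strip(g0, 135), tolerance = 1e-12)
})

test_that("wavelet energies are a unit partition with sensible extremes", {
  set.seed(4)
  roi <- matrix(runif(24 * 24), 24)
  te <- tefFeatures(roi)
  expect_length(te, 13)
  expect_true(all(te >= 0))
  expect_equal(sum(te), 1)
  # constant: all energy in the approximation
  tc <- tefFeatures(matrix(0.4, 16, 16))
  expect_equal(tc[["tef_approx"]], 1)
  expect_equal(sum(tc[1:12]), 0)
  # 1-px checkerboard: diagonal detail dominates every detail subband
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2) * 1.0
  tcb <- tefFeatures(cb)
  details <- tcb[setdiff(names(tcb), c("tef_approx", "tef_l1_d"))]
  expect_true(all(tcb[["tef_l1_d"]] > details))
  expect_error(tefFeatures(matrix(0.5, 10, 10)), "16")
})

test_that("the combined vector is 123 long, deterministic and discriminative", {
  fx <- diskROI(radiusPx = 8, seed = 40)
  fv <- extractFeatures(fx$roi, fx$truth)
  expect_length(fv, 123)
  expect_identical(names(fv), featureNames())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extractFeatures(fx$roi, fx$truth))
  # tiny masks still produce a full vector (wavelet input is padded)
  tiny <- diskROI(radiusPx = 3, seed = 41)
  expect_length(extractFeatures(tiny$roi, tiny$truth), 123)
  # population contrast: malign-style nodules show higher intensity variance
  vb <- vm <- numeric(25)
  for (k in 1:25) {
    set.seed(200 + k)
    n <- 31; ctr <- 16
    dk <- diskMask(n, c(ctr, ctr), 9)
    st <- starMaskFixture(n, c(ctr, ctr), 8, 0.3, 5, seed = 300 + k)
    mkroi <- function(mask, noise) {
      px <- 0.15 + 0.4 * mask + matrix(rnorm(n * n, 0, noise), n, n)
      structure(list(pixels = pmin(pmax(px, 0), 1),
                     origin = c(row = 1L, col = 1L),
                     center = c(row = ctr, col = ctr),
                     candidate = data.frame(row = ctr, col = ctr,
                                            radius_px = 9)),
                class = "noduleROI")
    }
    vb[k] <- extractFeatures(mkroi(dk, 0.01), dk)[["ssf_variance"]]
    vm[k] <- extractFeatures(mkroi(st, 0.05), st)[["ssf_variance"]]
  }
  expect_gt(mean(vm), mean(vb))
})
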