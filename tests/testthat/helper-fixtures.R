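# Shared synthetic fixtures, built in code.

# A bright disk on a dark background with additive noise; returns the image,
# the truth mask and an all-interior "lung" mask (border cleared).
renderDiskImage <- function(n, centerRC, radiusPx, lo = 0.1, hi = 0.7,
                            noiseSD = 0.01, seed = 1) {
  set.seed(seed)
  dd <- sqrt(outer((seq_len(n) - centerRC[1])^2,
                   (seq_len(n) - centerRC[2])^2, "+"))
  truth <- (dd <= radiusPx) * 1L
  img <- lo + (hi - lo) * truth + matrix(rnorm(n * n, 0, noiseSD), n, n)
  img <- pmin(pmax(img, 0), 1)
  lung <- matrix(0L, n, n)
  lung[8:(n - 7), 8:(n - 7)] <- 1L
  list(img = img, truth = truth, lung = lung)
}

# Rasterized disk mask.
diskMask <- function(n, centerRC, radiusPx) {
  dd <- sqrt(outer((seq_len(n) - centerRC[1])^2,
                   (seq_len(n) - centerRC[2])^2, "+"))
  (dd <= radiusPx) * 1L
}

# Star-convex mask with outward spicules, independent of the package's
# generator internals (used to test shape features against construction).
starMaskFixture <- function(n, centerRC, r0, amplitude, harmonics, seed) {
  set.seed(seed)
  a <- rnorm(harmonics); phi <- runif(harmonics, 0, 2 * pi)
  ii <- outer(seq_len(n) - centerRC[1], rep(1, n))
  jj <- outer(rep(1, n), seq_len(n) - centerRC[2])
  theta <- atan2(jj, ii)
  s <- matrix(0, n, n)
  for (k in seq_len(harmonics)) s <- s + a[k] * cos((7 + k) * theta + phi[k])
  s <- pmax(s / max(abs(s)), 0)
  (sqrt(ii^2 + jj^2) <= r0 * (1 + amplitude * s)) * 1L
}

# A disk-on-background ROI wrapped as a noduleROI (centre of the ROI).
diskROI <- function(radiusPx, lo = 0.1, contrast = 5, noiseSD = 0.02,
                    seed = 1) {
  set.seed(seed)
  n <- 2L * as.integer(ceiling(1.5 * radiusPx)) + 1L
  ctr <- (n + 1L) %/% 2L
  truth <- diskMask(n, c(ctr, ctr), radiusPx)
  px <- pmin(pmax(lo + lo * (contrast - 1) * truth +
                    matrix(rnorm(n * n, 0, noiseSD), n, n), 0), 1)
  roi <- structure(list(pixels = px, origin = c(row = 1L, col = 1L),
                        center = c(row = ctr, col = ctr),
                        candidate = data.frame(row = ctr, col = ctr,
                                               radius_px = radiusPx)),
                   class = "noduleROI")
  list(roi = roi, truth = truth)
}

# Brute-force GLCM by explicit pair counting (independent oracle).
bruteGLCM <- function(roi, levels, distance, angle) {
  q <- pmin(floor(roi * levels) + 1L, levels)
  dim(q) <- dim(roi)
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  M <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q))
        M[q[i, j], q[i2, j2]] <- M[q[i, j], q[i2, j2]] + 1
    }
  }
  M <- M + t(M)
  M / sum(M)
}

# Two separable Gaussian blobs in d dimensions.  By default the classes
# differ on the first axis only; allDims = TRUE spreads the separation over
# every axis, so it survives per-feature standardization (standardizing a
# single separable axis rescales it to unit variance like the noise axes).
gaussianBlobs <- function(nPerClass, d = 5, sep = 2, seed = 1,
                          allDims = FALSE) {
  set.seed(seed)
  mu <- if (allDims) rep(sep / 2, d) else c(sep / 2, rep(0, d - 1))
  X <- rbind(matrix(rnorm(nPerClass * d, -mu), ncol = d, byrow = TRUE),
             matrix(rnorm(nPerClass * d, mu), ncol = d, byrow = TRUE))
  y <- rep(c("benign", "malign"), each = nPerClass)
  list(X = X, y = y)
}
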