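# Stage III feature computation: the 123-element feature vector.
# Layout: 6 first-order statistical features (SSF), 16 shape-based features
# (SBF), 88 co-occurrence texture features (GTF: 22 descriptors x 4 angles),
# 13 wavelet subband energy features (TEF).

.ssfNames <- c("ssf_mean", "ssf_sd", "ssf_variance", "ssf_skewness",
               "ssf_kurtosis", "ssf_entropy")

.sbfNames <- c("sbf_area", "sbf_perimeter", "sbf_circularity",
               "sbf_eccentricity", "sbf_solidity", "sbf_extent",
               "sbf_equiv_diameter", "sbf_major_axis", "sbf_minor_axis",
               "sbf_aspect_ratio", "sbf_convex_area", "sbf_convex_perimeter",
               "sbf_convexity", "sbf_compactness", "sbf_radial_mean",
               "sbf_radial_sd")

.gtfDescriptors <- c("autocorrelation", "contrast", "correlation",
                     "cluster_prominence", "cluster_shade", "dissimilarity",
                     "asm", "entropy", "homogeneity", "max_probability",
                     "sum_of_squares", "sum_average", "sum_entropy",
                     "sum_variance", "difference_variance",
                     "difference_entropy", "imc1", "imc2",
                     "inverse_difference", "inverse_difference_norm",
                     "idm_norm", "max_correlation")

.tefNames <- c(paste0("tef_l", rep(1:4, each = 3), "_",
                      rep(c("h", "v", "d"), 4)), "tef_approx")

#' Names of the 123 features, in canonical order
#'
#' Indices 1–6 are first-order statistics (SSF), 7–22 shape descriptors
#' (SBF), 23–110 co-occurrence texture (GTF, 22 descriptors angle-major over
#' 0, 45, 90, 135 degrees), 111–123 wavelet subband energies (TEF).
#'
#' @return character vector of length 123; stable across runs.
#' @export
featureNames <- function() {
  gtf <- as.vector(vapply(c(0, 45, 90, 135),
                          function(a) paste0("gtf_a", a, "_", .gtfDescriptors),
                          character(22)))
  c(.ssfNames, .sbfNames, gtf, .tefNames)
}

#' GLCM configuration
#'
#' @param distance pixel displacement (default 2).
#' @param angles displacement directions in degrees (default 0, 45, 90, 135).
#' @param levels gray quantization bins, equal width on \[0, 1\] (default 16).
#' @param symmetric add the transposed counts (default TRUE).
#' @param normalized scale the matrix to sum 1 (default TRUE).
#' @return a validated list of class `glcmConfig`.
#' @export
glcmConfig <- function(distance = 2L, angles = c(0, 45, 90, 135),
                       levels = 16L, symmetric = TRUE, normalized = TRUE) {
  distance <- as.integer(distance); levels <- as.integer(levels)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be among 0, 45, 90, 135 degrees", call. = FALSE)
  structure(list(distance = distance, angles = angles, levels = levels,
                 symmetric = symmetric, normalized = normalized),
            class = "glcmConfig")
}

#' First-order statistical features (SSF)
#'
#' Mean, standard deviation, variance, skewness, kurtosis (population
#' moments) and histogram entropy in bits over 256 equal-width bins on
#' \[0, 1\].  Skewness and kurtosis of a zero-variance sample are 0 by
#' convention so feature vectors stay finite.
#'
#' @param values numeric vector of intensities (the ROI pixels inside the
#'   nodule mask), at least 2 values.
#' @return named numeric of length 6.
#' @export
ssfFeatures <- function(values) {
  if (length(values) < 2L) stop("need at least 2 pixels", call. = FALSE)
  m <- mean(values)
  v <- mean((values - m)^2)   # population variance
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((values - m)^3) / s^3
    kurt <- mean((values - m)^4) / s^4
  } else {
    skew <- 0; kurt <- 0
  }
  b <- pmin(floor(values * 256) + 1L, 256L)
  p <- tabulate(b, 256L) / length(values)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  c(ssf_mean = m, ssf_sd = s, ssf_variance = v, ssf_skewness = skew,
    ssf_kurtosis = kurt, ssf_entropy = ent)
}

# Sub-pixel outer contour of a mask by marching squares at level 0.5,
# smoothed with a circular moving average so the staircase does not bias
# length estimates (a digital disk's contour then measures within ~0.5% of
# 2*pi*r).  Returns list(x, y) closed implicitly.
.maskContour <- function(mask, smooth = 5L) {
  padded <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  cl <- contourLines(x = seq_len(nrow(padded)) - 1,
                     y = seq_len(ncol(padded)) - 1, z = padded, levels = 0.5)
  if (!length(cl)) return(NULL)
  # keep the longest contour (outer boundary of the main component)
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  x <- p$x; y <- p$y; n <- length(x)
  if (n > 2L * smooth) {
    k <- rep(1 / smooth, smooth)
    x <- stats::filter(c(x[(n - smooth + 1):n], x, x[1:smooth]), k,
                       sides = 2)[(smooth + 1):(smooth + n)]
    y <- stats::filter(c(y[(n - smooth + 1):n], y, y[1:smooth]), k,
                       sides = 2)[(smooth + 1):(smooth + n)]
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

.polyLength <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

.polyArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Shape-based features (SBF)
#'
#' Sixteen geometric descriptors of a binary nodule mask: area (px^2),
#' perimeter (px, smoothed sub-pixel contour), circularity `4*pi*A/P^2`,
#' eccentricity, solidity, extent, equivalent diameter, major/minor ellipse
#' axes, aspect ratio, convex area, convex perimeter, convexity (convex
#' perimeter / perimeter), compactness `P^2/A`, and the mean and standard
#' deviation of the boundary-to-centroid radial distance (boundary
#' irregularity: spiculated masks have a larger radial spread and lower
#' circularity than disks of equal area).
#'
#' @param mask nonempty 0/1 matrix, a single connected component.
#' @return named numeric of length 16.
#' @export
sbfFeatures <- function(mask) {
  mask <- checkMask(mask)
  area <- sum(mask)
  if (area == 0) stop("empty mask has no shape", call. = FALSE)
  idx <- which(mask == 1L, arr.ind = TRUE)
  ci <- mean(idx[, 1]); cj <- mean(idx[, 2])
  # second central moments with the 1/12 pixel-extent correction
  mu20 <- mean((idx[, 1] - ci)^2) + 1 / 12
  mu02 <- mean((idx[, 2] - cj)^2) + 1 / 12
  mu11 <- mean((idx[, 1] - ci) * (idx[, 2] - cj))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 1e-12)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  majorAxis <- 4 * sqrt(l1)
  minorAxis <- 4 * sqrt(l2)
  contour <- .maskContour(mask)
  if (is.null(contour) || length(contour$x) < 3) {
    perim <- 4 * sqrt(area)  # degenerate: fall back to square estimate
    cx <- idx[, 1]; cy <- idx[, 2]
  } else {
    perim <- .polyLength(contour$x, contour$y)
    cx <- contour$x; cy <- contour$y
  }
  hull <- chull(cx, cy)
  hx <- cx[hull]; hy <- cy[hull]
  convexArea <- max(.polyArea(hx, hy), area)
  convexPerimeter <- .polyLength(hx, hy)
  bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  radial <- sqrt((cx - ci)^2 + (cy - cj)^2)
  rmean <- mean(radial)
  rsd <- sqrt(mean((radial - rmean)^2))
  c(sbf_area = area,
    sbf_perimeter = perim,
    sbf_circularity = 4 * pi * area / perim^2,
    sbf_eccentricity = ecc,
    sbf_solidity = area / convexArea,
    sbf_extent = area / bbox,
    sbf_equiv_diameter = sqrt(4 * area / pi),
    sbf_major_axis = majorAxis,
    sbf_minor_axis = minorAxis,
    sbf_aspect_ratio = majorAxis / minorAxis,
    sbf_convex_area = convexArea,
    sbf_convex_perimeter = convexPerimeter,
    sbf_convexity = convexPerimeter / perim,
    sbf_compactness = perim^2 / area,
    sbf_radial_mean = rmean,
    sbf_radial_sd = rsd)
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes the ROI to `levels` equal-width bins on \[0, 1\], counts ordered
#' pixel pairs at the displacement given by `distance` and `angle`
#' (0 degrees = same row, +distance columns; 45 = up-right; 90 = up;
#' 135 = up-left), symmetrizes by adding the transpose, and normalizes to
#' sum 1.
#'
#' @param roi numeric matrix in \[0, 1\].
#' @param config a [glcmConfig()].
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcmMatrix <- function(roi, config = glcmConfig(), angle = 0) {
  stopifnot(inherits(config, "glcmConfig"))
  d <- config$distance; L <- config$levels
  q <- pmin(floor(roi * L) + 1L, L)
  dim(q) <- dim(roi)
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
                "135" = c(-d, -d),
                stop("angle must be 0, 45, 90 or 135", call. = FALSE))
  nr <- nrow(q); nc <- ncol(q)
  if (max(1L, 1L - off[1]) > min(nr, nr - off[1]) ||
      max(1L, 1L - off[2]) > min(nc, nc - off[2]))
    stop("ROI smaller than the displacement vector", call. = FALSE)
  i1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  j1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- q[i1, j1, drop = FALSE]
  b <- q[i1 + off[1], j1 + off[2], drop = FALSE]
  counts <- tabulate((a - 1L) * L + b, nbins = L * L)
  M <- matrix(counts, L, L, byrow = TRUE)
  if (config$symmetric) M <- M + t(M)
  if (config$normalized) {
    s <- sum(M)
    if (s == 0) stop("no valid pixel pairs", call. = FALSE)
    M <- M / s
  }
  M
}

# The 22 texture descriptors of one normalized, symmetric GLCM.
# Entropies are in bits.  Degenerate denominators (zero marginal variance
# or entropy) yield 0 so vectors stay finite.
glcmFeatures <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(L) * px); my <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(L) - my)^2 * py))
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  # p_{x+y}: k = 2..2L ; p_{x-y}: k = 0..L-1
  sums <- i + j; diffs <- abs(i - j)
  pxy <- vapply(2:(2 * L), function(k) sum(P[sums == k]), numeric(1))
  pxmy <- vapply(0:(L - 1), function(k) sum(P[diffs == k]), numeric(1))
  SA <- sum((2:(2 * L)) * pxy)
  nzs <- pxy > 0
  SE <- -sum(pxy[nzs] * log2(pxy[nzs]))
  SV <- sum(((2:(2 * L)) - SA)^2 * pxy)
  DA <- sum((0:(L - 1)) * pxmy)
  DV <- sum(((0:(L - 1)) - DA)^2 * pxmy)
  nzd <- pxmy > 0
  DE <- -sum(pxmy[nzd] * log2(pxmy[nzd]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pp <- outer(px, py)
  nzp <- P > 0 & pp > 0
  hxy1 <- -sum(P[nzp] * log2(pp[nzp]))
  nzq <- pp > 0
  hxy2 <- -sum(pp[nzq] * log2(pp[nzq]))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - ent))))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mx * my) / (sx * sy) else 0
  # maximal correlation coefficient: sqrt of the second largest eigenvalue
  # of Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
  keep <- px > 0 & py > 0   # identical marginals for a symmetric GLCM
  maxcor <- 0
  if (sum(keep) >= 2) {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    A <- Pk / pxk                    # rows divided by px
    B <- sweep(Pk, 2, pyk, "/")      # columns divided by py
    Q <- A %*% t(B)
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) maxcor <- sqrt(max(0, min(1, ev[2])))
  }
  c(autocorrelation = sum(i * j * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    cluster_prominence = sum((i + j - mx - my)^4 * P),
    cluster_shade = sum((i + j - mx - my)^3 * P),
    dissimilarity = sum(abs(i - j) * P),
    asm = sum(P^2),
    entropy = ent,
    homogeneity = sum(P / (1 + (i - j)^2)),
    max_probability = max(P),
    sum_of_squares = sum((i - mx)^2 * P),
    sum_average = SA,
    sum_entropy = SE,
    sum_variance = SV,
    difference_variance = DV,
    difference_entropy = DE,
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_norm = sum(P / (1 + abs(i - j) / L)),
    idm_norm = sum(P / (1 + (i - j)^2 / L^2)),
    max_correlation = maxcor)
}

#' Co-occurrence texture features (GTF)
#'
#' The 22 descriptors of [glcmFeatures] evaluated on the GLCM of each of
#' the four angles, concatenated angle-major (all 22 at 0 degrees, then 45,
#' 90, 135): 88 features.
#'
#' @param roi numeric matrix in \[0, 1\] (typically the masked bounding box).
#' @param config a [glcmConfig()].
#' @return named numeric of length 88.
#' @export
gtfFeatures <- function(roi, config = glcmConfig()) {
  out <- lapply(config$angles, function(a) {
    f <- glcmFeatures(glcmMatrix(roi, config, a))
    names(f) <- paste0("gtf_a", a, "_", names(f))
    f
  })
  unlist(out)
}

#' Wavelet subband energy features (TEF)
#'
#' Four-level 2D discrete wavelet decomposition (Daubechies-2 basis,
#' symmetric extension).  The 13 features are the relative energies (sum of
#' squared coefficients over total subband energy) of the 12 detail
#' subbands (horizontal, vertical, diagonal at each of 4 levels) plus the
#' level-4 approximation; they are nonnegative and sum to 1.
#'
#' @param roi numeric matrix, at least 16 x 16.
#' @return named numeric of length 13.
#' @export
tefFeatures <- function(roi) {
  if (nrow(roi) < 16L || ncol(roi) < 16L)
    stop("wavelet energy features require an ROI of at least 16 x 16 pixels",
         call. = FALSE)
  energies <- numeric(13)
  a <- roi
  for (lev in 1:4) {
    w <- dwt2(a)
    k <- (lev - 1) * 3
    energies[k + 1] <- sum(w$LH^2)  # horizontal detail
    energies[k + 2] <- sum(w$HL^2)  # vertical detail
    energies[k + 3] <- sum(w$HH^2)  # diagonal detail
    a <- w$LL
  }
  energies[13] <- sum(a^2)
  tot <- sum(energies)
  rel <- if (tot > 0) energies / tot else c(rep(0, 12), 1)
  names(rel) <- .tefNames
  rel
}

#' Extract the full 123-feature vector for one nodule
#'
#' Concatenates, in canonical order, the first-order statistics of the ROI
#' pixels inside the nodule mask (SSF), the shape descriptors of the mask
#' (SBF), and the texture (GTF) and wavelet energy (TEF) features of the
#' masked bounding box (the ROI multiplied by the mask, cropped to the mask
#' extent and, for the wavelet transform, zero-padded to the 16-pixel
#' minimum).
#'
#' @param roi `noduleROI` from [extractROI()] or a numeric matrix.
#' @param mask 0/1 nodule mask aligned to `roi`.
#' @param config a [glcmConfig()].
#' @return named numeric of length 123 (order of [featureNames()]).
#' @export
extractFeatures <- function(roi, mask, config = glcmConfig()) {
  px <- if (inherits(roi, "noduleROI")) roi$pixels else asPixels(roi, "roi")
  mask <- checkMask(mask, dim(px))
  if (sum(mask) < 2L)
    stop("nodule mask must contain at least 2 pixels", call. = FALSE)
  ssf <- tryCatch(ssfFeatures(px[mask == 1L]),
                  error = function(e) stop("SSF failed: ", conditionMessage(e),
                                           call. = FALSE))
  sbf <- tryCatch(sbfFeatures(mask),
                  error = function(e) stop("SBF failed: ", conditionMessage(e),
                                           call. = FALSE))
  idx <- which(mask == 1L, arr.ind = TRUE)
  i0 <- min(idx[, 1]); i1 <- max(idx[, 1])
  j0 <- min(idx[, 2]); j1 <- max(idx[, 2])
  mbb <- (px * mask)[i0:i1, j0:j1, drop = FALSE]
  # displacement must fit: grow tiny boxes symmetrically with zeros
  minSide <- max(config$distance + 1L, 4L)
  mbbG <- .padToSize(mbb, minSide, minSide)
  gtf <- tryCatch(gtfFeatures(mbbG, config),
                  error = function(e) stop("GTF failed: ", conditionMessage(e),
                                           call. = FALSE))
  tef <- tryCatch(tefFeatures(.padToSize(mbb, 16L, 16L)),
                  error = function(e) stop("TEF failed: ", conditionMessage(e),
                                           call. = FALSE))
  out <- c(ssf, sbf, gtf, tef)
  names(out) <- featureNames()
  stopifnot(length(out) == 123L)
  out
}

# Zero-pad a matrix symmetrically to at least nr x nc.
.padToSize <- function(m, nr, nc) {
  if (nrow(m) >= nr && ncol(m) >= nc) return(m)
  out <- matrix(0, max(nr, nrow(m)), max(nc, ncol(m)))
  oi <- (nrow(out) - nrow(m)) %/% 2L
  oj <- (ncol(out) - ncol(m)) %/% 2L
  out[oi + seq_len(nrow(m)), oj + seq_len(ncol(m))] <- m
  out
}
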