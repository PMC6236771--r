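# Stage I enhancement: median denoising, Laplacian sharpening, histogram
# equalization.  All operations accept a CTSlice or a plain numeric matrix
# and return the same container; outputs always stay in [0, 1].

#' Enhancement configuration
#'
#' @param medianKernel odd window size (pixels) for the median filter.
#' @param sharpenWeight nonnegative Laplacian subtraction weight; 0 disables
#'   sharpening.
#' @param equalizeBins number of histogram bins (>= 2) for equalization.
#' @return a validated list of class `enhanceConfig`.
#' @export
enhanceConfig <- function(medianKernel = 3L, sharpenWeight = 0.5,
                          equalizeBins = 256L) {
  medianKernel <- as.integer(medianKernel)
  if (medianKernel < 3L || medianKernel %% 2L == 0L)
    stop("medianKernel must be odd and >= 3", call. = FALSE)
  if (sharpenWeight < 0) stop("sharpenWeight must be >= 0", call. = FALSE)
  equalizeBins <- as.integer(equalizeBins)
  if (equalizeBins < 2L) stop("equalizeBins must be >= 2", call. = FALSE)
  structure(list(medianKernel = medianKernel, sharpenWeight = sharpenWeight,
                 equalizeBins = equalizeBins), class = "enhanceConfig")
}

#' Median denoising
#'
#' Replaces each pixel by the median of its `kernel` x `kernel`
#' neighborhood (constant-time median via EBImage; the filter works on the
#' 16-bit quantized intensity scale, so results agree with the exact
#' neighborhood median to within 1/65535).
#'
#' @param x `CTSlice` or numeric matrix in \[0, 1\].
#' @param kernel odd window size >= 3.
#' @return same container as `x`.
#' @export
medianDenoise <- function(x, kernel = 3L) {
  px <- asPixels(x)
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L)
    stop("kernel must be odd and >= 3", call. = FALSE)
  out <- EBImage::medianFilter(px, (kernel - 1L) %/% 2L)
  likeInput(x, clip01(matrix(as.numeric(out), nrow(px), ncol(px))))
}

#' Laplacian sharpening
#'
#' Computes `out = clip(in - weight * L(in), 0, 1)` where `L` is the
#' 4-neighbor Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]` applied with
#' reflect padding.  Subtracting the Laplacian boosts intensity steps, which
#' sharpens nodule contours; `weight = 0` is the identity.
#'
#' @param x `CTSlice` or numeric matrix in \[0, 1\].
#' @param weight nonnegative scalar.
#' @return same container as `x`.
#' @export
laplacianSharpen <- function(x, weight = 0.5) {
  px <- asPixels(x)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (weight == 0) return(x)
  p <- reflectPad(px, 1L)
  nr <- nrow(px); nc <- ncol(px)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  lap <- p[i - 1, j] + p[i + 1, j] + p[i, j - 1] + p[i, j + 1] - 4 * p[i, j]
  likeInput(x, clip01(px - weight * lap))
}

#' Histogram equalization
#'
#' Standard CDF-mapping equalization on a binned histogram: each pixel is
#' mapped to the empirical CDF value of its intensity bin.  The mapping is
#' monotone nondecreasing in input intensity; output is in \[0, 1\].
#'
#' @param x `CTSlice` or numeric matrix in \[0, 1\].
#' @param bins number of histogram bins (>= 2).
#' @return same container as `x`.
#' @export
histEqualize <- function(x, bins = 256L) {
  px <- asPixels(x)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  b <- pmin(floor(px * bins) + 1L, bins)
  h <- tabulate(b, bins)
  cdf <- cumsum(h) / length(px)
  likeInput(x, matrix(cdf[b], nrow(px), ncol(px)))
}

#' Full enhancement chain
#'
#' Composition median denoise -> Laplacian sharpen -> histogram equalize.
#' Denoising precedes differentiation so the Laplacian does not amplify
#' noise; equalization runs last so downstream intensity thresholds (the
#' lung extraction bands) see contrast-normalized input.
#'
#' @param x `CTSlice` or numeric matrix in \[0, 1\].
#' @param config an [enhanceConfig()].
#' @return same container as `x`.
#' @export
enhance <- function(x, config = enhanceConfig()) {
  stopifnot(inherits(config, "enhanceConfig"))
  out <- medianDenoise(x, config$medianKernel)
  out <- laplacianSharpen(out, config$sharpenWeight)
  histEqualize(out, config$equalizeBins)
}
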