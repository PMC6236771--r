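# Candidate nodule detection: gradient circular Hough transform over three
# radius bands, with greedy nonmaximum suppression.

#' Radius search bands
#'
#' The three canonical radius search ranges, in millimetres: small 3–12,
#' medium 10–20, large 15–45.  These are treated literally as radius ranges
#' (they are configurable; the corresponding dataset size *categories* are
#' diameters <10 / 10–20 / >20 mm).
#'
#' @return named list of `c(min_mm, max_mm)` pairs.
#' @export
radiusBands <- function() {
  list(small = c(3, 12), medium = c(10, 20), large = c(15, 45))
}

#' CHT detection parameters
#'
#' @param scoreThreshold minimum accumulator score as a fraction of the
#'   ideal (unit-weight) circumference vote mass `2*pi*r` (default 0.3).
#' @param edgeFraction voting pixels are those with Sobel gradient magnitude
#'   at least this fraction of the per-slice maximum (default 0.2); votes
#'   are weighted by the normalized magnitude, so faint noise gradients
#'   contribute little even when they pass the cut.
#' @param smoothSigma Gaussian pre-smoothing of the image before gradients
#'   are taken, in pixels.  The default `NULL` matches the smoothing to the
#'   band scale (`max(2, 0.2 * min band radius in px)`): equalization
#'   amplifies pixel noise, and for large nodules the smoothing also rounds
#'   a spiculated margin so its vote mass concentrates at the centre.
#' @param minCenterDistPx suppression distance floor in pixels (default 5;
#'   the effective pairwise distance is `max(minCenterDistPx,` smaller
#'   candidate radius`)`).
#' @return a validated list of class `chtParams`.
#' @export
chtParams <- function(scoreThreshold = 0.3, edgeFraction = 0.2,
                      smoothSigma = NULL, minCenterDistPx = 5) {
  if (scoreThreshold < 0) stop("scoreThreshold must be >= 0", call. = FALSE)
  if (edgeFraction <= 0 || edgeFraction >= 1)
    stop("edgeFraction must be in (0, 1)", call. = FALSE)
  if (!is.null(smoothSigma) && smoothSigma < 0)
    stop("smoothSigma must be >= 0", call. = FALSE)
  structure(list(scoreThreshold = scoreThreshold,
                 edgeFraction = edgeFraction, smoothSigma = smoothSigma,
                 minCenterDistPx = minCenterDistPx), class = "chtParams")
}

# Sobel gradients with reflect padding; returns list(gx, gy) where gx is the
# derivative along rows and gy along columns.
.sobel <- function(px) {
  p <- reflectPad(px, 1L)
  nr <- nrow(px); nc <- ncol(px)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  gx <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  gy <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  list(gx = gx, gy = gy)
}

# Convert a band in mm to an integer pixel radius grid, rounding outward.
.bandRadiiPx <- function(band, spacingMM) {
  rmin <- max(1L, as.integer(floor(band[1] / spacingMM)))
  rmax <- as.integer(ceiling(band[2] / spacingMM))
  if (rmax < 1L)
    stop("radius band collapses to a zero-pixel range at spacing ",
         spacingMM, " mm", call. = FALSE)
  seq.int(rmin, rmax)
}

#' Circular Hough transform candidate detection
#'
#' Gradient-based circular Hough voting over integer radii spanning the
#' band (converted to pixels at the slice spacing, rounded outward).  Edge
#' pixels inside the lung mask vote along their gradient direction — toward
#' brighter intensity, i.e. toward the centre of a bright nodule — at every
#' radius in the grid.  Per radius the accumulator is 3x3 box-summed and
#' normalized by `2*pi*r`; local maxima at or above the score threshold
#' whose centre lies inside the lung mask become candidates.  Deterministic
#' for fixed input.
#'
#' @param x `CTSlice` (preferred: carries its mm spacing) or numeric matrix;
#'   typically the masked lung image from [luvemExtract()].
#' @param lungMask 0/1 matrix aligned to `x`.
#' @param band `c(min_mm, max_mm)` radius range in millimetres, e.g. one of
#'   [radiusBands()].
#' @param params a [chtParams()].
#' @param spacingMM pixel spacing; defaults to the slice's own.
#' @return data.frame with columns `row`, `col`, `radius_px`, `radius_mm`,
#'   `score`, sorted by descending score.
#' @export
chtDetect <- function(x, lungMask, band, params = chtParams(),
                      spacingMM = NULL) {
  px <- asPixels(x)
  mask <- checkMask(lungMask, dim(px), "lungMask")
  stopifnot(inherits(params, "chtParams"))
  if (is.null(spacingMM))
    spacingMM <- if (is(x, "CTSlice")) pixelSpacing(x) else 0.7
  radii <- .bandRadiiPx(band, spacingMM)
  sigma <- if (is.null(params$smoothSigma))
    max(2, 0.2 * radii[1]) else params$smoothSigma
  if (sigma > 0)
    px <- matrix(as.numeric(EBImage::gblur(px, sigma)), nrow(px), ncol(px))
  g <- .sobel(px)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # voting is restricted to the lung interior: a rim is eroded off the mask
  # so the (arbitrarily strong) lung-boundary step cannot vote, and gradient
  # magnitudes are normalized within that interior so nodule and vessel
  # edges set the weight scale
  rim <- max(2L, as.integer(ceiling(2 * sigma)) + 1L)
  inner <- EBImage::erode(mask, EBImage::makeBrush(2L * rim + 1L, "disc"))
  w <- mag
  w[inner == 0] <- 0
  mmax <- max(w)
  if (mmax == 0) mmax <- 1
  w <- w / mmax
  w[w < params$edgeFraction] <- 0
  peaks <- cpp_cht(g$gx, g$gy, w, mask, radii, params$scoreThreshold)
  out <- as.data.frame(peaks)
  out$radius_mm <- out$radius_px * spacingMM
  out <- out[order(-out$score, out$row, out$col, out$radius_px), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("row", "col", "radius_px", "radius_mm", "score")]
}

#' Greedy nonmaximum suppression of circle candidates
#'
#' Scans candidates in descending score order and keeps one iff its centre
#' is at least `max(minCenterDistPx, min(radius_kept, radius_candidate))`
#' pixels away from every already-kept centre.  Stable and deterministic.
#'
#' @param cands data.frame as returned by [chtDetect()], sorted by
#'   descending score.
#' @param minCenterDistPx distance floor in pixels.
#' @return the kept subset, same columns and order discipline.
#' @export
nonmaxSuppress <- function(cands, minCenterDistPx = 5) {
  if (nrow(cands) == 0) return(cands)
  keep <- integer(0)
  for (k in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in keep) {
      d <- sqrt((cands$row[k] - cands$row[j])^2 +
                (cands$col[k] - cands$col[j])^2)
      if (d < max(minCenterDistPx,
                  min(cands$radius_px[k], cands$radius_px[j]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, k)
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect candidates across all three radius bands
#'
#' Runs [chtDetect()] for each band of [radiusBands()], annotates each
#' candidate with the band that produced it, and applies a single global
#' [nonmaxSuppress()] over the pooled, score-sorted list.
#'
#' @inheritParams chtDetect
#' @param bands named list of bands (default [radiusBands()]).
#' @return data.frame with the [chtDetect()] columns plus `band`.
#' @export
detectAllBands <- function(x, lungMask, params = chtParams(),
                           bands = radiusBands(), spacingMM = NULL) {
  per <- lapply(names(bands), function(nm) {
    d <- chtDetect(x, lungMask, bands[[nm]], params, spacingMM)
    if (nrow(d)) d$band <- nm else d$band <- character(0)
    d
  })
  all <- do.call(rbind, per)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(row = integer(0), col = integer(0),
                      radius_px = numeric(0), radius_mm = numeric(0),
                      score = numeric(0), band = character(0)))
  }
  all <- all[order(-all$score, all$row, all$col, all$radius_px), ,
             drop = FALSE]
  rownames(all) <- NULL
  nonmaxSuppress(all, params$minCenterDistPx)
}
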