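# Lung volume extraction (LUVEM), the Otsu baseline, and the Jaccard/Dice
# overlap metrics.

#' LUVEM configuration
#'
#' @param low,high intensity band: pixels with `low < value < high` on the
#'   enhanced image are candidate lung tissue (defaults 0.25 and 0.65).
#' @param erodeRadius,dilateRadius disk structuring-element radii (pixels)
#'   for the erode-then-dilate morphology step.
#' @return a validated list of class `luvemConfig`.
#' @export
luvemConfig <- function(low = 0.25, high = 0.65, erodeRadius = 2L,
                        dilateRadius = 4L) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1", call. = FALSE)
  if (erodeRadius < 1 || dilateRadius < 1)
    stop("structuring-element radii must be >= 1", call. = FALSE)
  structure(list(low = low, high = high,
                 erodeRadius = as.integer(erodeRadius),
                 dilateRadius = as.integer(dilateRadius)),
            class = "luvemConfig")
}

# Remove candidate components 4-connected to the image border.
.clearBorder <- function(mask) {
  lab <- cpp_label(mask, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  if (length(border)) mask[lab %in% border] <- 0L
  mask
}

# Erode, dilate (disk structuring elements), then fill interior holes.
.morphology <- function(mask, erodeRadius, dilateRadius) {
  if (!any(mask == 1L)) return(mask)
  m <- EBImage::erode(mask, EBImage::makeBrush(2L * erodeRadius + 1L, "disc"))
  m <- EBImage::dilate(m, EBImage::makeBrush(2L * dilateRadius + 1L, "disc"))
  storage.mode(m) <- "integer"
  cpp_fill_holes(m)
}

#' Lung volume extraction (LUVEM)
#'
#' Dual-threshold lung-field segmentation on the enhanced slice:
#' 1. pixels with intensity strictly inside `(low, high)` are candidate
#'    lung (after equalization the lung fields are mid-dark; body and bone
#'    exceed `high`);
#' 2. any candidate component 4-connected to the image border is removed
#'    (clears background air and bright edge artifacts);
#' 3. binary erosion then dilation with disk structuring elements, then
#'    interior hole filling (vessels and nodules inside the lung become
#'    part of the lung field);
#' 4. gray-scale restoration: the slice masked by the lung mask.
#'
#' @param x enhanced `CTSlice` or numeric matrix in \[0, 1\].
#' @param config a [luvemConfig()].
#' @return list with `mask` (0/1 integer matrix), `lungImage` (same
#'   container as `x`, zero outside the mask), and `empty` (flag; an empty
#'   mask after morphology yields a warning, not an error, so batch runs
#'   survive degenerate slices).
#' @export
luvemExtract <- function(x, config = luvemConfig()) {
  stopifnot(inherits(config, "luvemConfig"))
  px <- asPixels(x)
  cand <- (px > config$low & px < config$high) * 1L
  cand <- .clearBorder(cand)
  mask <- .morphology(cand, config$erodeRadius, config$dilateRadius)
  empty <- !any(mask == 1L)
  if (empty)
    warning("LUVEM produced an empty lung mask", call. = FALSE)
  list(mask = mask, lungImage = likeInput(x, px * mask), empty = empty)
}

#' Otsu-threshold lung extraction (baseline)
#'
#' Global Otsu threshold; the lung side is the below-threshold side.  The
#' same border clearing and morphology as [luvemExtract()] are applied so
#' the two methods are comparable.
#'
#' @param x enhanced `CTSlice` or numeric matrix in \[0, 1\].
#' @param config a [luvemConfig()]; only the morphology radii are used.
#' @return same structure as [luvemExtract()].
#' @export
otsuExtract <- function(x, config = luvemConfig()) {
  px <- asPixels(x)
  if (length(unique(as.vector(px))) < 2L)
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  thr <- EBImage::otsu(px, range = c(0, 1), levels = 256L)
  cand <- (px < thr) * 1L
  cand <- .clearBorder(cand)
  mask <- .morphology(cand, config$erodeRadius, config$dilateRadius)
  empty <- !any(mask == 1L)
  if (empty)
    warning("Otsu extraction produced an empty lung mask", call. = FALSE)
  list(mask = mask, lungImage = likeInput(x, px * mask), empty = empty,
       threshold = thr)
}

#' Jaccard and Dice overlap coefficients
#'
#' `jaccard(a, b) = |a & b| / |a | b|`; `dice(a, b) = 2|a & b| / (|a| + |b|)`.
#' Both are 1 when the two masks are both empty, and satisfy
#' `dice = 2 J / (1 + J)`.
#'
#' @param a,b 0/1 masks of identical shape.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- checkMask(a, arg = "a"); b <- checkMask(b, dim(a), arg = "b")
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' @rdname jaccard
#' @export
dice <- function(a, b) {
  a <- checkMask(a, arg = "a"); b <- checkMask(b, dim(a), arg = "b")
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}
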