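# Raster I/O for slices and masks.

#' Min–max intensity normalization
#'
#' Rescales a numeric matrix to \[0, 1\] by its own minimum and maximum.
#' A constant matrix maps to all zeros by convention (the range is
#' degenerate, so any constant would do; zero keeps masks and thresholds
#' predictable).  Already-normalized data spanning \[0, 1\] pass through
#' unchanged, so the operation is idempotent.
#'
#' @param x numeric matrix.
#' @return numeric matrix in \[0, 1\].
#' @export
normalizeMinMax <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(x), ncol(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Read a grayscale raster image as a CTSlice
#'
#' Reads an 8- or 16-bit grayscale PNG, min–max normalizes the intensities
#' (same contract as [readDicomSlice()]), and attaches the pixel spacing
#' passed as an argument (raster formats carry no physical spacing).
#'
#' @param path path to a grayscale PNG file.
#' @param spacingMM physical pixel spacing in millimetres.
#' @return A [CTSlice-class].
#' @export
readImageSlice <- function(path, spacingMM = 0.7) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 2L) a <- a[, , 1]  # gray + alpha
    else stop("color image: convert to grayscale before reading",
              call. = FALSE)
  }
  CTSlice(normalizeMinMax(a), spacingMM = spacingMM,
          sliceId = sub("\\.[^.]*$", "", basename(path)))
}

#' Write / read a binary mask losslessly
#'
#' Masks are stored as 8-bit grayscale PNGs with values {0, 255}; the round
#' trip is exact.
#'
#' @param mask 0/1 matrix.
#' @param path PNG path.
#' @return `writeMask` returns `path` invisibly; `readMask` returns an
#'   integer 0/1 matrix.
#' @export
writeMask <- function(mask, path) {
  m <- checkMask(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' @rdname writeMask
#' @param shape optional `c(rows, cols)`; an error is raised when the file
#'   does not match.
#' @export
readMask <- function(path, shape = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- (a > 0.5) * 1L
  if (!is.null(shape) && !identical(dim(m), as.integer(shape)))
    stop(sprintf("mask in %s has shape %dx%d, expected %dx%d", path,
                 nrow(m), ncol(m), shape[1], shape[2]), call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Write a CTSlice (or intensity matrix) as a grayscale PNG
#'
#' @param x `CTSlice` or numeric matrix in \[0, 1\].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
writeImageSlice <- function(x, path) {
  px <- asPixels(x)
  png::writePNG(px, path)
  invisible(path)
}
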