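# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Round half away from zero
#'
#' The display convention used by the performance reports; base `round()`
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Accept a CTSlice or a plain numeric matrix; return the pixel matrix.
asPixels <- function(x, arg = "x") {
  if (is(x, "CTSlice")) return(pixels(x))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("`%s` must be a CTSlice or a numeric matrix", arg),
       call. = FALSE)
}

# Rewrap a result matrix in the input's container (CTSlice in, CTSlice out).
likeInput <- function(template, px) {
  if (is(template, "CTSlice"))
    new("CTSlice", pixels = px, spacingMM = template@spacingMM,
        sliceId = template@sliceId)
  else px
}

# Validate a binary mask, optionally against an expected shape.
checkMask <- function(mask, shape = NULL, arg = "mask") {
  if (!is.matrix(mask) || !(is.numeric(mask) || is.logical(mask)))
    stop(sprintf("`%s` must be a matrix of 0/1 values", arg), call. = FALSE)
  m <- mask * 1L
  if (!all(m %in% c(0L, 1L)))
    stop(sprintf("`%s` must be strictly binary (0/1)", arg), call. = FALSE)
  if (!is.null(shape) && !identical(dim(m), as.integer(shape)))
    stop(sprintf("`%s` has shape %dx%d, expected %dx%d", arg,
                 nrow(m), ncol(m), shape[1], shape[2]), call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

# Reflect-pad a matrix by `k` pixels on every side (edge mirror without
# repeating the border sample).
reflectPad <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  if (k >= nr || k >= nc) stop("padding exceeds image size", call. = FALSE)
  ri <- c((k + 1):2, 1:nr, (nr - 1):(nr - k))
  ci <- c((k + 1):2, 1:nc, (nc - 1):(nc - k))
  x[ri, ci, drop = FALSE]
}

# log(sum(exp(x))) without overflow; x a numeric vector.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
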