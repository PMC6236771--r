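# Single-level 2D discrete wavelet transform, Daubechies-2 (D4) basis,
# symmetric (half-point reflect) boundary extension.  Only analysis is
# needed: the texture features use subband energies, not reconstruction.

.db2Lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db2Hi <- rev(.db2Lo) * c(1, -1, 1, -1)  # quadrature mirror filter

# Filter the columns of M with `f` after symmetric extension, then
# downsample by 2.  Output has floor((nrow(M) + 3) / 2) rows.
.dwtCols <- function(M, f) {
  m <- nrow(M)
  ext <- rbind(M[3:1, , drop = FALSE], M, M[m:(m - 2), , drop = FALSE])
  full <- f[1] * ext[1:(m + 3), , drop = FALSE] +
          f[2] * ext[2:(m + 4), , drop = FALSE] +
          f[3] * ext[3:(m + 5), , drop = FALSE] +
          f[4] * ext[4:(m + 6), , drop = FALSE]
  full[seq.int(2L, m + 3L, by = 2L), , drop = FALSE]
}

#' One level of the 2D discrete wavelet transform (Daubechies-2)
#'
#' Separable analysis: rows then columns, symmetric boundary extension,
#' dyadic downsampling.  Returns the four subbands: `LL` (approximation),
#' `LH` (horizontal detail), `HL` (vertical detail), `HH` (diagonal
#' detail).  The high-pass filter has zero sum, so a constant input yields
#' exactly zero detail coefficients.
#'
#' @param x numeric matrix, at least 4 x 4.
#' @return list of four coefficient matrices.
#' @export
dwt2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 4L, ncol(x) >= 4L)
  lo <- .dwtCols(x, .db2Lo)
  hi <- .dwtCols(x, .db2Hi)
  list(LL = t(.dwtCols(t(lo), .db2Lo)),
       LH = t(.dwtCols(t(hi), .db2Lo)),
       HL = t(.dwtCols(t(lo), .db2Hi)),
       HH = t(.dwtCols(t(hi), .db2Hi)))
}
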