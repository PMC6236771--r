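# Minimal single-frame DICOM support.
#
# The pipeline only needs uncompressed single-frame gray-level images with
# Rows/Columns, BitsAllocated, PixelRepresentation, PixelSpacing,
# RescaleSlope/Intercept and PixelData, in explicit or implicit VR little
# endian.  Sequences, encapsulated (compressed) transfer syntaxes and
# multi-frame objects are out of scope and rejected with an error.

.dcmTag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcmLongVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse a DICOM byte stream into a named list of raw values keyed by
# "GGGG,EEEE".  `explicit` refers to the main dataset; the file meta group
# (0002) is always explicit per the standard.
.dcmParse <- function(bytes) {
  n <- length(bytes)
  pos <- 1L
  if (n > 132 && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4,
                              signed = TRUE, endian = "little")
  # sniff explicitness of the first element at `pos`
  sniffExplicit <- function(at) {
    if (at + 7L > n) return(TRUE)
    vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
    grepl("^[A-Z]{2}$", vr)
  }
  out <- list()
  explicitMain <- NA
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group == 2L) {
      explicit <- TRUE  # file meta group is always explicit VR
    } else {
      if (is.na(explicitMain)) explicitMain <- sniffExplicit(pos)
      explicit <- explicitMain
    }
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .dcmLongVRs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len < 0 || (vr == "SQ"))
      stop("unsupported DICOM element (sequence or undefined length): tag ",
           .dcmTag(group, elem), call. = FALSE)
    start <- pos + hdr
    if (start + len - 1L > n)
      stop("truncated DICOM element at tag ", .dcmTag(group, elem),
           call. = FALSE)
    val <- if (len > 0) bytes[start:(start + len - 1L)] else raw(0)
    out[[.dcmTag(group, elem)]] <- val
    pos <- start + len
  }
  out
}

.dcmString <- function(el) {
  if (is.null(el) || length(el) == 0) return(NULL)
  trimws(rawToChar(el))
}

.dcmUint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el, "integer", n = length(el) %/% 2L, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a single-frame DICOM CT slice
#'
#' Reads an uncompressed single-frame gray-level DICOM file (explicit or
#' implicit VR little endian), applies the stored rescale slope/intercept,
#' and min–max normalizes intensities to \[0, 1\].  A constant image maps to
#' all zeros by convention.  Pixel spacing is taken from the PixelSpacing
#' attribute (first component); when absent, `defaultSpacingMM` is used and
#' a warning is issued (the detection radius bands are specified in
#' millimetres, so a spacing is always required downstream).
#'
#' @param path path to the DICOM file.
#' @param defaultSpacingMM fallback pixel spacing in mm when the file has no
#'   spacing attribute (default 0.7, a typical chest field of view at
#'   512 pixels).
#' @return A [CTSlice-class].
#' @seealso [writeDicomSlice()] for the matching synthetic-fixture writer.
#' @export
readDicomSlice <- function(path, defaultSpacingMM = 0.7) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  el <- .dcmParse(bytes)
  nfr <- .dcmString(el[["0028,0008"]])
  if (!is.null(nfr) && as.integer(nfr) > 1L)
    stop("multi-frame DICOM is not supported: ", path, call. = FALSE)
  rows <- .dcmUint16(el[["0028,0010"]])
  cols <- .dcmUint16(el[["0028,0011"]])
  bits <- .dcmUint16(el[["0028,0100"]])
  if (is.null(rows) || is.null(cols) || is.null(el[["7FE0,0010"]]))
    stop("not a readable single-frame DICOM image: ", path, call. = FALSE)
  if (is.null(bits)) bits <- 16L
  pixrep <- .dcmUint16(el[["0028,0103"]])
  signed <- !is.null(pixrep) && pixrep == 1L
  pd <- el[["7FE0,0010"]]
  npx <- as.integer(rows) * as.integer(cols)
  raw2num <- switch(as.character(bits),
    "8"  = as.numeric(readBin(pd, "integer", n = npx, size = 1,
                              signed = signed)),
    "16" = as.numeric(readBin(pd, "integer", n = npx, size = 2,
                              signed = signed, endian = "little")),
    stop("unsupported BitsAllocated: ", bits, call. = FALSE))
  if (length(raw2num) < npx)
    stop("pixel data shorter than Rows x Columns: ", path, call. = FALSE)
  slope <- .dcmString(el[["0028,1053"]]); slope <- if (is.null(slope)) 1 else as.numeric(slope)
  inter <- .dcmString(el[["0028,1052"]]); inter <- if (is.null(inter)) 0 else as.numeric(inter)
  v <- raw2num * slope + inter
  # DICOM pixel data is row-major (fills rows first)
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  px <- normalizeMinMax(px)
  sp <- .dcmString(el[["0028,0030"]])
  if (is.null(sp)) {
    warning("no PixelSpacing in ", basename(path), "; using default ",
            defaultSpacingMM, " mm", call. = FALSE)
    spacing <- defaultSpacingMM
  } else {
    spacing <- as.numeric(strsplit(sp, "\\\\")[[1]][1])
  }
  CTSlice(px, spacingMM = spacing,
          sliceId = sub("\\.[^.]*$", "", basename(path)))
}

.dcmElement <- function(group, element, vr, value) {
  hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% .dcmLongVRs) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2, endian = "little"), value)
  }
}

.dcmText <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}

#' Write a minimal synthetic single-frame DICOM file
#'
#' Serializes a 16-bit gray-level image as an uncompressed explicit-VR
#' little-endian DICOM file carrying only the attributes the reader needs
#' (Rows, Columns, BitsAllocated, PixelRepresentation, PixelSpacing,
#' rescale slope/intercept, PixelData).  Intended for synthetic fixtures
#' and round-trip tests, not for clinical interchange.
#'
#' @param values numeric or integer matrix; values are stored as uint16
#'   after subtracting the recorded intercept and dividing by the slope.
#' @param path output path.
#' @param spacingMM pixel spacing written to PixelSpacing; `NULL` omits the
#'   attribute (exercises the reader's fallback).
#' @param slope,intercept rescale attributes to record.
#' @return `path`, invisibly.
#' @export
writeDicomSlice <- function(values, path, spacingMM = 0.7, slope = 1,
                            intercept = 0) {
  stopifnot(is.matrix(values))
  stored <- round((values - intercept) / slope)
  if (min(stored) < 0 || max(stored) > 65535)
    stop("stored values must fit uint16; adjust slope/intercept",
         call. = FALSE)
  pd <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  meta <- .dcmElement(0x0002, 0x0010, "UI",
                      .dcmText("1.2.840.10008.1.2.1"))
  ds <- c(
    .dcmElement(0x0028, 0x0008, "IS", .dcmText("1")),
    .dcmElement(0x0028, 0x0010, "US",
                writeBin(nrow(values), raw(), size = 2, endian = "little")),
    .dcmElement(0x0028, 0x0011, "US",
                writeBin(ncol(values), raw(), size = 2, endian = "little")),
    if (!is.null(spacingMM))
      .dcmElement(0x0028, 0x0030, "DS",
                  .dcmText(sprintf("%g\\%g", spacingMM, spacingMM))),
    .dcmElement(0x0028, 0x0100, "US",
                writeBin(16L, raw(), size = 2, endian = "little")),
    .dcmElement(0x0028, 0x0103, "US",
                writeBin(0L, raw(), size = 2, endian = "little")),
    .dcmElement(0x0028, 0x1052, "DS", .dcmText(sprintf("%g", intercept))),
    .dcmElement(0x0028, 0x1053, "DS", .dcmText(sprintf("%g", slope))),
    .dcmElement(0x7FE0, 0x0010, "OW", pd)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
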