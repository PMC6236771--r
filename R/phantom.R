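# Seeded synthetic chest phantom: a bright body ellipse containing two dark
# lung fields with bright vessel segments and planted circular nodules
# (benign: round, smooth-edged, low internal variance; malign: spiculated
# star-convex boundary with higher internal variance), plus ground-truth
# masks and labels.  The geometry is chosen so that, after histogram
# equalization, lung-field intensities fall inside the (0.25, 0.65)
# extraction band while background air and the bright body fall outside or
# border-connected — emulating the intensity structure of real chest CT.

#' Phantom specification
#'
#' Intensity levels follow the contrast layout of chest CT after
#' normalization: dark background air, bright body ellipse, dark lung
#' fields, vessels and nodules in between.
#'
#' @param imageSize slice side in pixels (default 512).
#' @param spacingMM pixel spacing in millimetres (default 0.7).
#' @param nNodules nodules per slice when sizes are sampled.
#' @param sizeRangeMM nodule diameter range in mm (within \[3, 65\]).
#' @param malignFraction probability a sampled nodule is malign
#'   (default 116/220, the reference class balance).
#' @param lungLevel,bodyLevel,vesselLevel,noduleLevel,backgroundLevel base
#'   intensities of the tissue classes.
#' @param noiseSD global additive Gaussian noise.
#' @param benignNoiseSD,malignNoiseSD internal texture noise of the two
#'   nodule types (malign higher: malignancy is encoded as boundary
#'   irregularity plus texture variance).
#' @param spiculationAmplitude relative radial perturbation of malign
#'   boundaries (fraction of the radius).
#' @param spiculationHarmonics minimum number of angular harmonics (>= 8).
#' @param nVesselRange number of vessel segments per slice.
#' @param tableArtifact add a bright mid-intensity arc touching the lower
#'   image border (a scanner-table artifact that border clearing must
#'   remove).
#' @return a validated list of class `phantomSpec`.
#' @export
phantomSpec <- function(imageSize = 512L, spacingMM = 0.7, nNodules = 3L,
                        sizeRangeMM = c(3, 65), malignFraction = 116 / 220,
                        lungLevel = 0.15, bodyLevel = 0.75,
                        vesselLevel = 0.6, noduleLevel = 0.55,
                        backgroundLevel = 0.03, noiseSD = 0.02,
                        benignNoiseSD = 0.01, malignNoiseSD = 0.05,
                        spiculationAmplitude = 0.3,
                        spiculationHarmonics = 8L,
                        nVesselRange = c(5L, 15L), tableArtifact = TRUE) {
  if (sizeRangeMM[1] < 3 || sizeRangeMM[2] > 65 ||
      sizeRangeMM[1] > sizeRangeMM[2])
    stop("nodule diameters must lie within [3, 65] mm", call. = FALSE)
  if (malignFraction < 0 || malignFraction > 1)
    stop("malignFraction must be in [0, 1]", call. = FALSE)
  if (spiculationHarmonics < 8L)
    stop("spiculated boundaries use at least 8 harmonics", call. = FALSE)
  structure(list(imageSize = as.integer(imageSize), spacingMM = spacingMM,
                 nNodules = as.integer(nNodules), sizeRangeMM = sizeRangeMM,
                 malignFraction = malignFraction, lungLevel = lungLevel,
                 bodyLevel = bodyLevel, vesselLevel = vesselLevel,
                 noduleLevel = noduleLevel, backgroundLevel = backgroundLevel,
                 noiseSD = noiseSD, benignNoiseSD = benignNoiseSD,
                 malignNoiseSD = malignNoiseSD,
                 spiculationAmplitude = spiculationAmplitude,
                 spiculationHarmonics = as.integer(spiculationHarmonics),
                 nVesselRange = as.integer(nVesselRange),
                 tableArtifact = tableArtifact),
            class = "phantomSpec")
}

.ellipseMask <- function(n, centerRC, semiRC) {
  ii <- (seq_len(n) - centerRC[1]) / semiRC[1]
  jj <- (seq_len(n) - centerRC[2]) / semiRC[2]
  (outer(ii^2, jj^2, "+") <= 1) * 1L
}

# Star-convex spiculated mask: a round core of radius r0 with outward
# spicules, r(theta) = r0 (1 + A * max(s(theta), 0)) where s is a random
# harmonic series (harmonics hmin..hmin+4) normalized to max 1.  Spicules
# extend outward only — real spiculation is star-like boundary extensions
# from a compact core, and the core circle is what circle detection keys on.
.starMask <- function(n, centerRC, r0, amplitude, hmin) {
  h <- hmin:(hmin + 4L)
  a <- rnorm(length(h)); phi <- runif(length(h), 0, 2 * pi)
  ii <- outer(seq_len(n) - centerRC[1], rep(1, n))
  jj <- outer(rep(1, n), seq_len(n) - centerRC[2])
  theta <- atan2(jj, ii)
  s <- matrix(0, n, n)
  for (k in seq_along(h)) s <- s + a[k] * cos(h[k] * theta + phi[k])
  s <- pmax(s / max(abs(s), 1e-9), 0)
  rad <- r0 * (1 + amplitude * s)
  (sqrt(ii^2 + jj^2) <= rad) * 1L
}

.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  matrix(as.numeric(EBImage::gblur(m, sigma)), nrow(m), ncol(m))
}

# Render one nodule into `img`; returns list(img, mask).
.renderNodule <- function(img, lungMask, centerRC, radiusPx, label, spec) {
  n <- nrow(img)
  if (label == "malign") {
    mask <- .starMask(n, centerRC, radiusPx, spec$spiculationAmplitude,
                      spec$spiculationHarmonics)
    alpha <- .gaussBlur(mask, 0.5)
    noiseSD <- spec$malignNoiseSD
  } else {
    ii <- outer(seq_len(n) - centerRC[1], rep(1, n))
    jj <- outer(rep(1, n), seq_len(n) - centerRC[2])
    mask <- (sqrt(ii^2 + jj^2) <= radiusPx) * 1L
    alpha <- .gaussBlur(mask, 1.2)
    noiseSD <- spec$benignNoiseSD
  }
  level <- spec$noduleLevel + rnorm(sum(mask), 0, noiseSD)
  img <- img * (1 - alpha) + spec$noduleLevel * alpha
  img[mask == 1L] <- level
  list(img = img, mask = mask)
}

#' Generate one phantom slice with ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair.  Nodules are placed fully
#' inside the lung fields, pairwise disjoint (with a 4-pixel clearance);
#' placement retries up to 200 times per nodule before failing with an
#' error suggesting fewer or smaller nodules.
#'
#' @param spec a [phantomSpec()].
#' @param seed RNG seed (mandatory; all randomness is scoped to it).
#' @param diametersMM optional nodule diameters in mm (overrides sampling).
#' @param labels optional labels (`benign` / `malign`) matching
#'   `diametersMM`.
#' @return list with `slice` ([CTSlice-class]), `lungMask` (0/1 matrix) and
#'   `nodules` — a list of `list(mask, center, diameterMM, label)` whose
#'   masks are pairwise disjoint subsets of the lung mask.
#' @export
phantomSlice <- function(spec = phantomSpec(), seed, diametersMM = NULL,
                         labels = NULL) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (missing(seed)) stop("phantomSlice requires a seed", call. = FALSE)
  withSeed(seed, .phantomSliceImpl(spec, diametersMM, labels, seed))
}

.phantomSliceImpl <- function(spec, diametersMM, labels, seed) {
  n <- spec$imageSize
  img <- matrix(spec$backgroundLevel, n, n)
  body <- .ellipseMask(n, c(0.50 * n, 0.50 * n), c(0.42 * n, 0.47 * n))
  img[body == 1L] <- spec$bodyLevel
  lungL <- .ellipseMask(n, c(0.50 * n, 0.30 * n), c(0.27 * n, 0.15 * n))
  lungR <- .ellipseMask(n, c(0.50 * n, 0.70 * n), c(0.27 * n, 0.15 * n))
  lungMask <- ((lungL + lungR) > 0) * 1L
  img[lungMask == 1L] <- spec$lungLevel
  if (isTRUE(spec$tableArtifact)) {
    arc <- .ellipseMask(n, c(1.12 * n, 0.5 * n), c(0.18 * n, 0.45 * n))
    arc[body == 1L] <- 0L
    img[arc == 1L] <- 0.45
  }
  # nodule placement first, so vessels can keep clear of the planted
  # shapes: a vessel fused to a nodule would silently change the ground
  # truth that the labels describe
  if (is.null(diametersMM)) {
    diametersMM <- runif(spec$nNodules, spec$sizeRangeMM[1],
                         spec$sizeRangeMM[2])
    labels <- ifelse(runif(spec$nNodules) < spec$malignFraction,
                     "malign", "benign")
  }
  stopifnot(length(labels) == length(diametersMM))
  placed <- list()
  for (k in seq_along(diametersMM)) {
    rPx <- diametersMM[k] / 2 / spec$spacingMM
    # spiculated boundaries extend to (1 + amplitude) * r: reserve for it
    rEff <- if (labels[k] == "malign")
      rPx * (1 + spec$spiculationAmplitude) else rPx
    margin <- as.integer(ceiling(rEff)) + 3L
    feas <- EBImage::erode(lungMask,
                           EBImage::makeBrush(2L * margin + 1L, "disc"))
    feasIdx <- which(feas == 1L)
    if (!length(feasIdx))
      stop("cannot place a ", round(diametersMM[k], 1),
           " mm nodule inside the lung fields; use fewer or smaller nodules",
           call. = FALSE)
    ok <- FALSE
    for (try in 1:200) {
      ctr <- as.vector(arrayInd(sample(feasIdx, 1), dim(lungMask)))
      clear <- TRUE
      for (p in placed) {
        if (sqrt(sum((ctr - p$center)^2)) < rEff + p$radiusPx + 4) {
          clear <- FALSE; break
        }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok)
      stop("nodule placement failed after 200 retries; ",
           "use fewer or smaller nodules", call. = FALSE)
    placed[[k]] <- list(center = ctr, radiusPx = rPx, rEff = rEff)
  }
  # vessels: random thick segments clipped to the lung fields, avoiding a
  # 3-px clearance zone around every planted nodule
  allowed <- lungMask
  for (p in placed) {
    ii <- outer(seq_len(n) - p$center[1], rep(1, n))
    jj <- outer(rep(1, n), seq_len(n) - p$center[2])
    allowed[sqrt(ii^2 + jj^2) <= p$rEff + 3] <- 0L
  }
  nv <- sample(spec$nVesselRange[1]:spec$nVesselRange[2], 1)
  inside <- which(lungMask == 1L)
  for (v in seq_len(nv)) {
    p0 <- arrayInd(sample(inside, 1), dim(lungMask))
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 0.02 * n, 0.08 * n)
    thick <- sample(1:3, 1)
    tpts <- seq(0, len, by = 0.5)
    ri <- round(p0[1] + tpts * cos(ang)); ci <- round(p0[2] + tpts * sin(ang))
    for (t in seq_along(tpts)) {
      i0 <- max(1, ri[t] - thick); i1 <- min(n, ri[t] + thick)
      j0 <- max(1, ci[t] - thick); j1 <- min(n, ci[t] + thick)
      if (i0 > i1 || j0 > j1) next
      blk <- img[i0:i1, j0:j1, drop = FALSE]
      sel <- allowed[i0:i1, j0:j1, drop = FALSE] == 1L
      blk[sel] <- spec$vesselLevel
      img[i0:i1, j0:j1] <- blk
    }
  }
  nodules <- vector("list", length(diametersMM))
  for (k in seq_along(diametersMM)) {
    ctr <- placed[[k]]$center
    rn <- .renderNodule(img, lungMask, ctr, placed[[k]]$radiusPx,
                        labels[k], spec)
    img <- rn$img
    mask <- rn$mask
    mask[lungMask == 0L] <- 0L  # guaranteed by placement margin
    nodules[[k]] <- list(mask = mask, center = c(row = ctr[1], col = ctr[2]),
                         diameterMM = diametersMM[k], label = labels[k])
  }
  img <- clip01(img + matrix(rnorm(n * n, 0, spec$noiseSD), n, n))
  list(slice = CTSlice(img, spacingMM = spec$spacingMM,
                       sliceId = paste0("phantom_", seed)),
       lungMask = lungMask, nodules = nodules)
}

#' Generate a labelled phantom dataset
#'
#' Draws nodule diameters per size band (`<10`, `10–20`, `>20` mm — default
#' counts 75/65/80 with 104 benign + 116 malign, the reference composition),
#' packs them onto slices, renders each slice with a seed derived from
#' `seed`, and returns a manifest.  With `dir` given, slices, lung masks and
#' nodule masks are written as PNGs plus a `manifest.csv`.
#'
#' @param nBenign,nMalign class counts.
#' @param sizeBins counts per diameter band `c(<10, 10-20, >20)`; must sum
#'   to `nBenign + nMalign`.
#' @param seed dataset seed.
#' @param spec a [phantomSpec()].
#' @param nodulesPerSlice maximum nodules rendered per slice (large nodules
#'   are packed fewer to a slice so placement stays feasible).
#' @param maxDiameterMM cap on sampled diameters (default the spec range).
#' @param dir optional output directory.
#' @param keepImages keep rendered slices in the returned object (default
#'   only when not writing to `dir`).
#' @return list with `manifest` (data.frame: slice_id, nodule, row, col,
#'   diameter_mm, band, label and file columns when written) and, when
#'   `keepImages`, `slices` — a list of [phantomSlice()] results.
#' @export
phantomDataset <- function(nBenign = 104L, nMalign = 116L,
                           sizeBins = c(75L, 65L, 80L), seed,
                           spec = phantomSpec(), nodulesPerSlice = 3L,
                           maxDiameterMM = NULL, dir = NULL,
                           keepImages = is.null(dir)) {
  if (missing(seed)) stop("phantomDataset requires a seed", call. = FALSE)
  total <- nBenign + nMalign
  if (sum(sizeBins) != total)
    stop("sizeBins must sum to nBenign + nMalign", call. = FALSE)
  if (is.null(maxDiameterMM)) maxDiameterMM <- spec$sizeRangeMM[2]
  plan <- withSeed(seed, {
    band <- rep(c("<10", "10-20", ">20"), times = sizeBins)
    lab <- sample(rep(c("benign", "malign"), times = c(nBenign, nMalign)))
    dia <- numeric(total)
    lo <- pmax(spec$sizeRangeMM[1], c(3, 10, 20.5))
    hi <- pmin(maxDiameterMM, c(9.99, 20, 65))
    names(lo) <- names(hi) <- c("<10", "10-20", ">20")
    for (b in unique(band)) {
      sel <- band == b
      dia[sel] <- runif(sum(sel), lo[[b]], min(hi[[b]], maxDiameterMM))
    }
    ord <- sample(total)
    data.frame(band = band[ord], label = lab[ord], diameter_mm = dia[ord])
  })
  # pack nodules onto slices: cap both the count and the summed radius
  rPx <- plan$diameter_mm / 2 / spec$spacingMM
  budget <- 0.12 * spec$imageSize
  slices <- list(); cur <- integer(0); curR <- 0
  assign_rows <- list()
  for (k in seq_len(nrow(plan))) {
    if (length(cur) >= nodulesPerSlice || curR + rPx[k] > budget) {
      assign_rows[[length(assign_rows) + 1]] <- cur
      cur <- integer(0); curR <- 0
    }
    cur <- c(cur, k); curR <- curR + rPx[k]
  }
  if (length(cur)) assign_rows[[length(assign_rows) + 1]] <- cur
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); rendered <- list()
  for (s in seq_along(assign_rows)) {
    rows <- assign_rows[[s]]
    ph <- phantomSlice(spec, seed = seed + s,
                       diametersMM = plan$diameter_mm[rows],
                       labels = plan$label[rows])
    sid <- sprintf("slice_%03d", s)
    files <- rep(NA_character_, length(rows))
    if (!is.null(dir)) {
      writeImageSlice(ph$slice, file.path(dir, paste0(sid, ".png")))
      writeMask(ph$lungMask, file.path(dir, paste0(sid, "_lung.png")))
      for (k in seq_along(rows)) {
        f <- file.path(dir, sprintf("%s_nodule_%d.png", sid, k))
        writeMask(ph$nodules[[k]]$mask, f)
        files[k] <- basename(f)
      }
    }
    manifest[[s]] <- data.frame(
      slice_id = sid, nodule = seq_along(rows),
      row = vapply(ph$nodules, function(x) x$center[["row"]], numeric(1)),
      col = vapply(ph$nodules, function(x) x$center[["col"]], numeric(1)),
      diameter_mm = plan$diameter_mm[rows], band = plan$band[rows],
      label = plan$label[rows], mask_file = files)
    if (keepImages) rendered[[sid]] <- ph
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  out <- list(manifest = manifest)
  if (keepImages) out$slices <- rendered
  out
}
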