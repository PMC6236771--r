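# Nodule segmentation: per-ROI self-organizing map pixel clustering.

#' SOM configuration
#'
#' Defaults: 4 nodes on a 1D chain (background, parenchyma texture,
#' vessel/edge, nodule), 20 epochs, learning rate decaying exponentially
#' 0.5 -> 0.01, neighborhood radius 2 -> 0.2.  The final neighborhood is
#' small enough that late updates are effectively winner-only; a larger
#' floor keeps pulling neighbouring prototypes toward the sample mean and
#' prevents a 2-node map from settling on two well-separated clusters.
#' The seed is mandatory: SOM training is the only stochastic step in the
#' pipeline.
#'
#' @param nNodes number of map units (>= 2), 1D chain topology.
#' @param epochs training passes over the sample set (>= 1).
#' @param lrInitial,lrFinal learning-rate schedule endpoints,
#'   `0 < lrFinal <= lrInitial <= 1`.
#' @param neighborhoodInitial,neighborhoodFinal neighborhood radius schedule
#'   endpoints (map units).
#' @param seed RNG seed for initialization and presentation order.
#' @return a validated list of class `somConfig`.
#' @export
somConfig <- function(nNodes = 4L, epochs = 20L, lrInitial = 0.5,
                      lrFinal = 0.01, neighborhoodInitial = 2,
                      neighborhoodFinal = 0.2, seed) {
  if (missing(seed)) stop("somConfig requires an explicit seed", call. = FALSE)
  nNodes <- as.integer(nNodes); epochs <- as.integer(epochs)
  if (nNodes < 2L) stop("nNodes must be >= 2", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (!(lrFinal > 0 && lrFinal <= lrInitial && lrInitial <= 1))
    stop("need 0 < lrFinal <= lrInitial <= 1", call. = FALSE)
  structure(list(nNodes = nNodes, epochs = epochs, lrInitial = lrInitial,
                 lrFinal = lrFinal,
                 neighborhoodInitial = neighborhoodInitial,
                 neighborhoodFinal = neighborhoodFinal,
                 seed = as.integer(seed)),
            class = "somConfig")
}

#' Extract a square ROI around a candidate nodule
#'
#' The ROI is a square sub-image of side `2 * ceiling(1.5 * radius_px) + 1`
#' (minimum 9) centred on the candidate; near the image border the window is
#' shifted to fit (it still contains the candidate centre).
#'
#' @param x `CTSlice` or numeric matrix.
#' @param candidate a one-row data.frame (or list) with `row`, `col`,
#'   `radius_px` — one row of [chtDetect()] output.
#' @return list of class `noduleROI` with `pixels` (matrix), `origin`
#'   (`c(row, col)` of the ROI's top-left pixel in slice coordinates),
#'   `center` (candidate centre in ROI coordinates), and `candidate`.
#' @export
extractROI <- function(x, candidate) {
  px <- asPixels(x)
  r <- candidate$radius_px[1]
  ci <- candidate$row[1]; cj <- candidate$col[1]
  if (ci < 1 || ci > nrow(px) || cj < 1 || cj > ncol(px))
    stop("candidate centre outside the slice", call. = FALSE)
  side <- max(9L, 2L * as.integer(ceiling(1.5 * r)) + 1L)
  if (side > nrow(px) || side > ncol(px))
    stop("ROI side ", side, " px exceeds the slice; candidate too large",
         call. = FALSE)
  half <- (side - 1L) %/% 2L
  i0 <- min(max(1L, as.integer(round(ci)) - half), nrow(px) - side + 1L)
  j0 <- min(max(1L, as.integer(round(cj)) - half), ncol(px) - side + 1L)
  structure(list(pixels = px[i0:(i0 + side - 1L), j0:(j0 + side - 1L)],
                 origin = c(row = i0, col = j0),
                 center = c(row = as.integer(round(ci)) - i0 + 1L,
                            col = as.integer(round(cj)) - j0 + 1L),
                 candidate = candidate[1, , drop = FALSE]),
            class = "noduleROI")
}

# Pixel feature vectors used for SOM clustering: raw intensity plus the
# 3x3 local mean (adds spatial context so single-pixel noise does not
# fragment clusters).
somPixelFeatures <- function(roiPixels) {
  p <- reflectPad(roiPixels, 1L)
  nr <- nrow(roiPixels); nc <- ncol(roiPixels)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  m3 <- (p[i - 1, j - 1] + p[i - 1, j] + p[i - 1, j + 1] +
         p[i, j - 1] + p[i, j] + p[i, j + 1] +
         p[i + 1, j - 1] + p[i + 1, j] + p[i + 1, j + 1]) / 9
  cbind(intensity = as.vector(roiPixels), mean3 = as.vector(m3))
}

#' Train a self-organizing map
#'
#' Classic online SOM on a 1D chain: per step the nearest prototype
#' (Euclidean) wins and all nodes move toward the sample with an
#' exponentially decaying learning rate and Gaussian neighborhood.
#' Prototypes are initialized by sampling `nNodes` training vectors;
#' initialization and presentation order are drawn under the config seed,
#' so training is fully deterministic given the seed.
#'
#' @param samples numeric matrix, one feature vector per row (at least
#'   `nNodes` rows).
#' @param config a [somConfig()].
#' @return A [SOMModel-class].
#' @export
somTrain <- function(samples, config) {
  stopifnot(inherits(config, "somConfig"))
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < config$nNodes)
    stop("need at least nNodes = ", config$nNodes, " samples, got ", n,
         call. = FALSE)
  ord <- withSeed(config$seed, {
    init <- sample.int(n, config$nNodes)
    pres <- as.vector(vapply(seq_len(config$epochs),
                             function(e) sample.int(n, n),
                             integer(n)))
    list(init = init, pres = pres)
  })
  W <- cpp_som_train(samples, config$nNodes, ord$init, ord$pres,
                     config$lrInitial, config$lrFinal,
                     config$neighborhoodInitial, config$neighborhoodFinal)
  new("SOMModel", weights = W, config = unclass(config))
}

#' Segment a nodule inside an ROI with a trained SOM
#'
#' Every ROI pixel is assigned to its nearest prototype.  The prototypes
#' are then split into a dark and a bright group at the largest gap in
#' their intensity ordering (several map nodes may share the bright nodule
#' intensity, so a single "brightest node" would fragment the nodule);
#' the bright group must intersect the candidate circle.  The nodule mask
#' is the largest 8-connected component of the bright-group pixels
#' containing the ROI centre (or, failing that, the component nearest to
#' it), with holes filled.
#'
#' @param roi a `noduleROI` from [extractROI()].
#' @param model a [SOMModel-class] trained on [somTrain()] features of the
#'   same dimensionality (typically the ROI's own pixels).
#' @return list with `labelMap` (integer matrix of cluster indices),
#'   `mask` (0/1 matrix, a single connected component or empty), and
#'   `degenerate` (flag: uniform ROI or empty nodule cluster; warned).
#' @export
somSegment <- function(roi, model) {
  stopifnot(inherits(roi, "noduleROI"), is(model, "SOMModel"))
  feats <- somPixelFeatures(roi$pixels)
  W <- model@weights
  if (ncol(feats) != ncol(W))
    stop("model feature dimensionality does not match the ROI features",
         call. = FALSE)
  # squared distance of every pixel to every prototype
  d2 <- outer(rowSums(feats^2), rowSums(W^2), "+") - 2 * feats %*% t(W)
  lab <- max.col(-d2, ties.method = "first")
  labelMap <- matrix(lab, nrow(roi$pixels), ncol(roi$pixels))
  nr <- nrow(labelMap); nc <- ncol(labelMap)
  ctr <- roi$center
  r <- max(1, roi$candidate$radius_px[1])
  dmat <- sqrt(outer((seq_len(nr) - ctr["row"])^2,
                     (seq_len(nc) - ctr["col"])^2, "+"))
  inCircle <- dmat <= r
  # Nodule cluster selection.  Candidate rule 1: cut the intensity-ordered
  # prototypes at their largest gap and take the bright side — but only if
  # that group is tight (its internal spread does not exceed the gap), which
  # merges map nodes that merely share the nodule intensity.  Otherwise
  # (e.g. a continuum of background intensities with no natural gap) rule 2:
  # the single cluster with the highest mean intensity among those present
  # under the candidate circle.
  proto <- W[, 1]
  ord <- order(proto)
  gaps <- diff(proto[ord])
  bright <- integer(0)
  if (length(gaps) && max(gaps) > 0) {
    cut <- which.max(gaps)
    cand <- ord[(cut + 1):length(ord)]
    if (diff(range(proto[cand])) <= max(gaps)) bright <- cand
  } else {
    bright <- seq_along(proto)  # all prototypes equal: degenerate
  }
  if (!length(bright) || !any(labelMap[inCircle] %in% bright)) {
    present <- sort(unique(lab[as.vector(inCircle)]))
    if (!length(present)) present <- sort(unique(lab))
    meanInt <- vapply(present, function(k) mean(roi$pixels[labelMap == k]),
                      numeric(1))
    bright <- present[which.max(meanInt)]
  }
  clusterMask <- (matrix(lab %in% bright, nr, nc)) * 1L
  degenerate <- FALSE
  if (all(clusterMask == 1L) || !any(clusterMask == 1L)) {
    degenerate <- TRUE
    warning("degenerate SOM segmentation (uniform ROI?)", call. = FALSE)
    if (!any(clusterMask == 1L))
      return(list(labelMap = labelMap,
                  mask = matrix(0L, nr, nc), degenerate = TRUE))
  }
  comp <- cpp_label(clusterMask, 8L)
  ctrLab <- comp[round(ctr["row"]), round(ctr["col"])]
  if (ctrLab == 0L) {
    # nearest component to the centre
    ds <- dmat; ds[comp == 0L] <- Inf
    ctrLab <- comp[which.min(ds)]
  }
  mask <- cpp_fill_holes((comp == ctrLab) * 1L)
  list(labelMap = labelMap, mask = mask, degenerate = degenerate)
}

#' Segment the nodule at a candidate with a per-ROI SOM
#'
#' Convenience wrapper implementing the per-region usage: extract the ROI,
#' train a SOM on the ROI's own pixel features, and segment.
#'
#' @inheritParams extractROI
#' @param config a [somConfig()].
#' @return the [somSegment()] result plus `roi`.
#' @export
segmentCandidate <- function(x, candidate, config) {
  roi <- extractROI(x, candidate)
  model <- somTrain(somPixelFeatures(roi$pixels), config)
  out <- somSegment(roi, model)
  out$roi <- roi
  out
}
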