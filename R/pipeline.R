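# Stage I–IV orchestration with per-stage artifacts.

#' Pipeline configuration
#'
#' Bundles every stage's configuration plus the run seed.  Unknown keys in
#' `...` or in a YAML config file are rejected so silent typos cannot
#' change a run.
#'
#' @param enhance an [enhanceConfig()].
#' @param luvem a [luvemConfig()].
#' @param cht a [chtParams()].
#' @param somNodes,somEpochs SOM size and training passes.
#' @param glcm a [glcmConfig()].
#' @param splitFraction component-rule split fraction (see
#'   [nComponentsRule()]).
#' @param sigma PNN spread: `"auto"` or a positive number.
#' @param priors PNN prior mode (see [pnnFit()]).
#' @param pcaGlobal fit PCA globally instead of per LOOCV fold.
#' @param seed run seed (drives SOM training and any sampling).
#' @return a validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(enhance = enhanceConfig(), luvem = luvemConfig(),
                           cht = chtParams(), somNodes = 4L, somEpochs = 20L,
                           glcm = glcmConfig(), splitFraction = 0.5,
                           sigma = "auto", priors = "uniform",
                           pcaGlobal = FALSE, seed = 1L) {
  structure(list(enhance = enhance, luvem = luvem, cht = cht,
                 somNodes = as.integer(somNodes),
                 somEpochs = as.integer(somEpochs), glcm = glcm,
                 splitFraction = splitFraction, sigma = sigma,
                 priors = priors, pcaGlobal = pcaGlobal,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments (stage configs as
#' nested maps of their constructor arguments).  Unknown keys raise an
#' error.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  args <- raw
  build <- function(key, ctor) {
    if (!is.null(raw[[key]])) do.call(ctor, raw[[key]]) else NULL
  }
  for (key in c("enhance", "luvem", "cht", "glcm")) {
    ctor <- switch(key, enhance = enhanceConfig, luvem = luvemConfig,
                   cht = chtParams, glcm = glcmConfig)
    v <- build(key, ctor)
    if (is.null(v)) args[[key]] <- NULL else args[[key]] <- v
  }
  do.call(pipelineConfig, args)
}

# Match detected candidates to planted/annotated nodule centres.  Returns,
# per truth row, the index of the best candidate within
# max(3, 0.5 * radius_px) pixels, or NA (a detection miss).
.matchCandidates <- function(cands, truth) {
  vapply(seq_len(nrow(truth)), function(k) {
    if (nrow(cands) == 0) return(NA_integer_)
    d <- sqrt((cands$row - truth$row[k])^2 + (cands$col - truth$col[k])^2)
    tol <- max(3, 0.5 * truth$radius_px[k])
    ok <- which(d <= tol)
    if (!length(ok)) return(NA_integer_)
    ok[which.max(cands$score[ok])]
  }, integer(1))
}

#' Run the full pipeline on a phantom dataset or a directory of slices
#'
#' Per slice: enhancement, lung volume extraction, candidate detection over
#' all radius bands, SOM segmentation of each nodule ROI, and feature
#' extraction.  Lung extraction and detection run on the fully enhanced
#' slice (the extraction thresholds assume contrast-normalized input);
#' segmentation and feature extraction run on the median-denoised slice,
#' whose intensities are faithful to the acquisition — histogram
#' equalization would stretch within-nodule noise across the gray scale and
#' distort both the cluster structure and the intensity statistics.  With a
#' labelled manifest the features are evaluated by leave-one-out
#' cross-validation and a size-stratified report is written.
#' Artifacts land in `outDir`: enhanced slices and lung masks (PNG),
#' `candidates.csv`, `features.csv`, `report.json` and `run_log.json`.
#'
#' Annotated nodules are matched to the closest detected candidate (within
#' half a radius, at least 3 px); unmatched nodules are logged as detection
#' misses and fall back to their annotated circle so the classification
#' stage still sees every labelled nodule.
#'
#' @param input result of [phantomDataset()] (with images kept) or a
#'   directory containing `manifest.csv` plus the PNG slices it references.
#' @param config a [pipelineConfig()].
#' @param outDir output directory; `NULL` keeps everything in memory.
#' @return list with `features` (data.frame: 123 feature columns +
#'   slice_id, label, diameter_mm), `candidates`, `detection` (per-nodule
#'   match log), and — when labels are present — `loocv` (see [loocv()]).
#' @export
runPipeline <- function(input, config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.character(input)) input <- .loadRunInput(input)
  manifest <- input$manifest
  slices <- input$slices
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  featRows <- list(); candRows <- list(); detRows <- list()
  for (sid in names(slices)) {
    ph <- slices[[sid]]
    mrows <- manifest[manifest$slice_id == sid, , drop = FALSE]
    enh <- enhance(ph$slice, config$enhance)
    den <- medianDenoise(ph$slice, config$enhance$medianKernel)
    lung <- luvemExtract(enh, config$luvem)
    cands <- detectAllBands(lung$lungImage, lung$mask, config$cht)
    if (nrow(cands)) cands$slice_id <- sid
    candRows[[sid]] <- cands
    truth <- data.frame(row = mrows$row, col = mrows$col,
                        radius_px = mrows$diameter_mm / 2 /
                          pixelSpacing(ph$slice))
    match <- .matchCandidates(cands, truth)
    for (k in seq_len(nrow(mrows))) {
      if (!is.na(match[k])) {
        cand <- cands[match[k], , drop = FALSE]
      } else {
        cand <- data.frame(row = truth$row[k], col = truth$col[k],
                           radius_px = truth$radius_px[k],
                           radius_mm = mrows$diameter_mm[k] / 2,
                           score = NA_real_, band = NA_character_)
      }
      somCfg <- somConfig(nNodes = config$somNodes,
                          epochs = config$somEpochs,
                          seed = config$seed + 1000L * k +
                            match(sid, names(slices)))
      seg <- withCallingHandlers(
        segmentCandidate(den, cand, somCfg),
        warning = function(w) invokeRestart("muffleWarning"))
      mask <- seg$mask
      if (sum(mask) < 5L) {
        # degenerate segmentation: fall back to the candidate circle
        nr <- nrow(seg$roi$pixels)
        ctr <- seg$roi$center
        dmat <- sqrt(outer((seq_len(nr) - ctr["row"])^2,
                           (seq_len(nr) - ctr["col"])^2, "+"))
        mask <- (dmat <= max(2, cand$radius_px[1])) * 1L
      }
      fv <- extractFeatures(seg$roi, mask, config$glcm)
      lab <- if ("label" %in% names(mrows)) mrows$label[k] else NA_character_
      featRows[[length(featRows) + 1]] <- data.frame(
        t(fv), slice_id = sid, label = lab,
        diameter_mm = mrows$diameter_mm[k], check.names = FALSE)
      detRows[[length(detRows) + 1]] <- data.frame(
        slice_id = sid, nodule = k, detected = !is.na(match[k]),
        center_err_px = if (!is.na(match[k]))
          sqrt((cand$row - truth$row[k])^2 + (cand$col - truth$col[k])^2)
        else NA_real_)
    }
  }
  features <- do.call(rbind, featRows)
  candidates <- do.call(rbind, candRows)
  detection <- do.call(rbind, detRows)
  out <- list(features = features, candidates = candidates,
              detection = detection, config = config)
  if (!is.null(features) && !all(is.na(features$label))) {
    X <- as.matrix(features[, featureNames()])
    out$loocv <- loocv(X, features$label, sizesMM = features$diameter_mm,
                       splitFraction = config$splitFraction,
                       sigma = config$sigma, priors = config$priors,
                       pcaGlobal = config$pcaGlobal, seed = config$seed)
  }
  if (!is.null(outDir)) .writeRunArtifacts(out, outDir)
  out
}

.loadRunInput <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- read.csv(mf)
  slices <- list()
  for (sid in unique(manifest$slice_id)) {
    slice <- readImageSlice(file.path(dir, paste0(sid, ".png")))
    lungFile <- file.path(dir, paste0(sid, "_lung.png"))
    lungMask <- if (file.exists(lungFile)) readMask(lungFile) else NULL
    slices[[sid]] <- list(slice = slice, lungMask = lungMask)
  }
  list(manifest = manifest, slices = slices)
}

.writeRunArtifacts <- function(run, outDir) {
  if (!is.null(run$candidates))
    write.csv(run$candidates, file.path(outDir, "candidates.csv"),
              row.names = FALSE)
  if (!is.null(run$features))
    write.csv(run$features, file.path(outDir, "features.csv"),
              row.names = FALSE)
  if (!is.null(run$detection))
    write.csv(run$detection, file.path(outDir, "detection.csv"),
              row.names = FALSE)
  if (!is.null(run$loocv)) {
    rep <- run$loocv$report
    payload <- list(
      confusion = list(TP = run$loocv$cm@TP, FP = run$loocv$cm@FP,
                       FN = run$loocv$cm@FN, TN = run$loocv$cm@TN),
      metrics = as.list(formatMetrics(rep)),
      auc = run$loocv$auc,
      size_report = run$loocv$sizeReport,
      sigma = unique(run$loocv$log$sigma),
      n_components = unique(run$loocv$log$n_components))
    jsonlite::write_json(payload, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(outDir)
}

#' Summarize a completed run directory
#'
#' Aggregates the serialized artifacts of [runPipeline()] into a compact
#' summary: detection recall, candidate counts, and — for labelled runs —
#' the performance criteria and the per-band table.
#'
#' @param runDir directory written by [runPipeline()].
#' @return list summary (also pretty-printed).
#' @export
runReport <- function(runDir) {
  out <- list()
  det <- file.path(runDir, "detection.csv")
  if (file.exists(det)) {
    d <- read.csv(det)
    out$n_nodules <- nrow(d)
    out$detection_recall <- mean(d$detected)
  }
  cand <- file.path(runDir, "candidates.csv")
  if (file.exists(cand)) out$n_candidates <- nrow(read.csv(cand))
  repf <- file.path(runDir, "report.json")
  if (file.exists(repf)) {
    out <- c(out, jsonlite::read_json(repf, simplifyVector = TRUE))
  } else {
    out$note <- "unlabelled run: detection-only report"
  }
  out
}
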