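# Confusion matrices, the six performance criteria, ROC/AUC, the
# leave-one-out protocol, and size-stratified reporting.

#' Build a confusion matrix from label vectors
#'
#' Positive class is `malign`: TP = malign predicted malign, TN = benign
#' predicted benign, FP = benign predicted malign, FN = malign predicted
#' benign.
#'
#' @param yTrue,yPred equal-length vectors with values in
#'   `{benign, malign}`.
#' @return A [ConfusionMatrix-class].
#' @export
confusion <- function(yTrue, yPred) {
  yTrue <- .asLabels(yTrue); yPred <- .asLabels(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  ConfusionMatrix(TP = sum(yTrue == "malign" & yPred == "malign"),
                  FP = sum(yTrue == "benign" & yPred == "malign"),
                  FN = sum(yTrue == "malign" & yPred == "benign"),
                  TN = sum(yTrue == "benign" & yPred == "benign"))
}

#' The six performance criteria of a confusion matrix
#'
#' Accuracy, sensitivity, specificity, positive and negative decision value
#' (precision of the positive/negative call) as percentages, and the F1
#' score as a fraction:
#' `Acc = 100 (TP+TN)/total`, `Sen = 100 TP/(TP+FN)`,
#' `Spc = 100 TN/(TN+FP)`, `PDV = 100 TP/(TP+FP)`,
#' `NDV = 100 TN/(TN+FN)`, `F1 = 2TP/(2TP+FP+FN)`.
#' Values are returned at full precision; [formatMetrics()] applies the
#' display convention (round half up to 2 decimals).  A metric with a zero
#' denominator is `NA`, never 0 or 100.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named list of class `performanceReport`.
#' @examples
#' formatMetrics(performanceMetrics(ConfusionMatrix(113, 6, 3, 98)))
#' @export
performanceMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  TP <- cm@TP; FP <- cm@FP; FN <- cm@FN; TN <- cm@TN
  total <- TP + FP + FN + TN
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    Acc = 100 * frac(TP + TN, total),
    Sen = 100 * frac(TP, TP + FN),
    Spc = 100 * frac(TN, TN + FP),
    PDV = 100 * frac(TP, TP + FP),
    NDV = 100 * frac(TN, TN + FN),
    F1  = frac(2 * TP, 2 * TP + FP + FN),
    cm  = cm
  ), class = "performanceReport")
}

#' Display-rounded performance criteria
#'
#' Applies the reporting convention — round half up to 2 decimals — to a
#' `performanceReport`.
#'
#' @param report result of [performanceMetrics()].
#' @return named numeric vector (Acc, Sen, Spc, PDV, NDV, F1).
#' @export
formatMetrics <- function(report) {
  stopifnot(inherits(report, "performanceReport"))
  v <- unlist(report[c("Acc", "Sen", "Spc", "PDV", "NDV", "F1")])
  roundHalfUp(v, 2)
}

#' @export
print.performanceReport <- function(x, ...) {
  v <- formatMetrics(x)
  cm <- x$cm
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d | Acc %.2f  Sen %.2f  Spc %.2f  PDV %.2f  NDV %.2f  F1 %.2f\n",
              cm@TP, cm@FP, cm@FN, cm@TN,
              v["Acc"], v["Sen"], v["Spc"], v["PDV"], v["NDV"], v["F1"]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (predict malign when
#' `score >= threshold`); AUC by the trapezoid rule, which equals the
#' normalized Mann–Whitney U statistic (ties counted half).
#'
#' @param scores malign posterior (or any monotone score) per case.
#' @param labels true labels in `{benign, malign}`; both classes required.
#' @return list with `curve` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- .asLabels(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  pos <- labels == "malign"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Leave-one-out cross-validation of the PCA + PNN classifier
#'
#' For each held-out case the PCA model and the PNN are fitted on the
#' remaining cases only (no leakage; `pcaGlobal = TRUE` mimics a single
#' global PCA fit instead).  The per-fold component count follows
#' [nComponentsRule()] on the training fold's smaller class, capped by the
#' data rank; sigma is selected per fold by [pnnSigmaSelect()] unless a
#' fixed value is given.
#'
#' @param X feature matrix (one row per nodule, e.g. 123 columns).
#' @param y labels in `{benign, malign}` (>= 2 cases per class).
#' @param sizesMM optional nodule diameters (mm) for the size-stratified
#'   report.
#' @param splitFraction passed to [nComponentsRule()] (default 0.5).
#' @param sigma `"auto"` (per-fold selection) or a fixed positive number.
#' @param priors as in [pnnFit()].
#' @param pcaGlobal fit PCA once on all data instead of per fold.
#' @param seed reserved for stochastic extensions; the protocol itself is
#'   deterministic (sigma ties resolve to the smallest value).
#' @return list with `cm` ([ConfusionMatrix-class]), `report`
#'   (`performanceReport`), `log` (one row per case: truth, prediction,
#'   posterior, sigma, components), `auc`, and `sizeReport` when `sizesMM`
#'   is given.
#' @export
loocv <- function(X, y, sizesMM = NULL, splitFraction = 0.5, sigma = "auto",
                  priors = "uniform", pcaGlobal = FALSE, seed = 1L) {
  X <- as.matrix(X)
  y <- .asLabels(y)
  n <- nrow(X)
  if (any(table(y) < 2L))
    stop("need at least 2 cases per class for leave-one-out", call. = FALSE)
  ruleK <- function(labs) {
    mc <- min(table(labs))
    if (mc >= 3) nComponentsRule(mc, splitFraction) else 1L
  }
  globalModel <- NULL
  if (pcaGlobal) {
    k <- min(ruleK(y), ncol(X), n - 1L)
    globalModel <- pcaFit(X, .capRank(X, k))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    fold <- tryCatch({
      model <- if (pcaGlobal) globalModel else {
        k <- min(ruleK(ytr), ncol(Xtr), nrow(Xtr) - 1L)
        pcaFit(Xtr, .capRank(Xtr, k))
      }
      Ztr <- pcaTransform(model, Xtr)
      Zte <- pcaTransform(model, X[i, , drop = FALSE])
      sg <- if (identical(sigma, "auto"))
        pnnSigmaSelect(Ztr, ytr, priors = priors)$sigma else sigma
      pnn <- pnnFit(Ztr, ytr, sg, priors = priors)
      pred <- pnnPredict(pnn, Zte)
      data.frame(case = i, truth = as.character(y[i]),
                 predicted = as.character(pred$label),
                 posterior_malign = pred$posterior_malign,
                 sigma = sg, n_components = model@nComponents)
    }, error = function(e) {
      stop("leave-one-out fold ", i, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    rows[[i]] <- fold
  }
  log <- do.call(rbind, rows)
  cm <- confusion(log$truth, log$predicted)
  out <- list(cm = cm, report = performanceMetrics(cm), log = log,
              auc = rocAuc(log$posterior_malign, log$truth)$auc)
  if (!is.null(sizesMM))
    out$sizeReport <- sizeStratifiedReport(log$truth, log$predicted, sizesMM)
  out
}

# Cap a requested component count by the rank of the standardized data.
.capRank <- function(X, k) {
  sds <- apply(X, 2, sd)
  scales <- ifelse(sds < 1e-12, 1, sds)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, scales, "/")
  d <- svd(Xs, nu = 0, nv = 0)$d
  rank <- sum(d > max(dim(Xs)) * .Machine$double.eps * d[1])
  max(1L, min(as.integer(k), rank))
}

#' Size-stratified performance report
#'
#' Partitions cases into the diameter bands `< 10 mm`, `10–20 mm` and
#' `> 20 mm` (intervals `[0, 10)`, `[10, 20]`, `(20, Inf)`) and reports the
#' confusion counts and the six criteria per band plus overall.  The band
#' matrices always sum to the overall matrix; an empty band is omitted with
#' a message.
#'
#' @param yTrue,yPred label vectors in `{benign, malign}`.
#' @param sizesMM nodule diameters in millimetres, one per case.
#' @return data.frame with columns `band`, `n`, `TP`, `FP`, `FN`, `TN`,
#'   `Acc`, `Sen`, `Spc`, `PDV`, `NDV`, `F1` (display-rounded).
#' @export
sizeStratifiedReport <- function(yTrue, yPred, sizesMM) {
  yTrue <- .asLabels(yTrue); yPred <- .asLabels(yPred)
  stopifnot(length(yTrue) == length(yPred),
            length(sizesMM) == length(yTrue))
  band <- ifelse(sizesMM < 10, "<10",
                 ifelse(sizesMM <= 20, "10-20", ">20"))
  bandLevels <- c("<10", "10-20", ">20")
  rows <- list()
  for (b in c(bandLevels, "overall")) {
    sel <- if (b == "overall") rep(TRUE, length(band)) else band == b
    if (!any(sel)) {
      message("size band ", b, " is empty; omitted from the report")
      next
    }
    cm <- confusion(yTrue[sel], yPred[sel])
    v <- formatMetrics(performanceMetrics(cm))
    rows[[b]] <- data.frame(band = b, n = sum(sel), TP = cm@TP, FP = cm@FP,
                            FN = cm@FN, TN = cm@TN, Acc = v["Acc"],
                            Sen = v["Sen"], Spc = v["Spc"], PDV = v["PDV"],
                            NDV = v["NDV"], F1 = v["F1"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
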