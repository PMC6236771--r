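# Probabilistic neural network (Parzen-window) benign/malign classifier.
# The pattern layer stores one unit per training example; class scores are
# Gaussian-kernel means (equal kernel width across classes and dimensions).

.pnnLevels <- c("benign", "malign")

.asLabels <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), .pnnLevels)
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "),
         " (expected benign/malign)", call. = FALSE)
  factor(y, levels = .pnnLevels)
}

#' Fit a probabilistic neural network
#'
#' Stores the training vectors verbatim (no iterative training).  Class
#' scores at prediction time are per-class kernel *means* by default
#' (equivalent to uniform class priors, so an imbalanced class cannot win
#' on pattern count alone); `priors = "proportional"` weights classes by
#' their training frequency instead.
#'
#' @param X numeric matrix of reduced feature vectors, one row per pattern.
#' @param y labels in `{benign, malign}`; both classes must be present.
#' @param sigma Gaussian spread (> 0).
#' @param priors `"uniform"` (default) or `"proportional"`.
#' @return A [PNNModel-class].
#' @export
pnnFit <- function(X, y, sigma, priors = c("uniform", "proportional")) {
  X <- as.matrix(X)
  y <- .asLabels(y)
  priors <- match.arg(priors)
  if (length(y) != nrow(X)) stop("one label per row required", call. = FALSE)
  if (any(table(y) < 1L))
    stop("both classes must be present in the training labels",
         call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  new("PNNModel", patterns = X, labels = y, sigma = sigma, priors = priors)
}

#' Predict with a probabilistic neural network
#'
#' For a query `x`, each class score is the mean over that class's stored
#' patterns of `exp(-||x - p||^2 / (2 sigma^2))` (log-domain computation, so
#' tiny kernels do not underflow); posteriors are the scores normalized to
#' sum 1 and the label is the argmax, with exact ties resolved to `benign`
#' (favor the non-cancer call on a tie).
#'
#' @param model a [PNNModel-class].
#' @param X query vector or matrix (one query per row).
#' @return data.frame with columns `label`, `posterior_benign`,
#'   `posterior_malign`.
#' @export
pnnPredict <- function(model, X) {
  stopifnot(is(model, "PNNModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  P <- model@patterns
  if (ncol(X) != ncol(P))
    stop("query width ", ncol(X), " does not match pattern width ", ncol(P),
         call. = FALSE)
  s2 <- 2 * model@sigma^2
  d2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P)
  d2[d2 < 0] <- 0
  logk <- -d2 / s2
  n <- nrow(P)
  logScore <- vapply(.pnnLevels, function(cl) {
    cols <- which(model@labels == cl)
    w <- if (model@priors == "uniform") -log(length(cols)) else -log(n)
    apply(logk[, cols, drop = FALSE], 1, logSumExp) + w
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logScore <- matrix(logScore, nrow = 1,
                                        dimnames = list(NULL, .pnnLevels))
  m <- apply(logScore, 1, max)
  post <- exp(logScore - m)
  post <- post / rowSums(post)
  label <- ifelse(post[, "malign"] > post[, "benign"], "malign", "benign")
  data.frame(label = factor(label, levels = .pnnLevels),
             posterior_benign = post[, "benign"],
             posterior_malign = post[, "malign"],
             row.names = NULL)
}

#' Select sigma by leave-one-out accuracy on the training set
#'
#' Evaluates a log-spaced sigma grid by leave-one-out accuracy over the
#' training patterns (each pattern scored against all others) and returns
#' the best value; ties resolve to the smallest sigma, so the choice is
#' deterministic.
#'
#' @param X training feature matrix.
#' @param y labels in `{benign, malign}`.
#' @param grid candidate sigmas (default 12 log-spaced values in
#'   \[0.05, 5\]).
#' @param priors as in [pnnFit()].
#' @return list with `sigma` (the selection) and `accuracy` (named vector of
#'   LOO accuracies over the grid).
#' @export
pnnSigmaSelect <- function(X, y,
                           grid = exp(seq(log(0.05), log(5),
                                          length.out = 12)),
                           priors = "uniform") {
  X <- as.matrix(X)
  y <- .asLabels(y)
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  d2[d2 < 0] <- 0
  diag(d2) <- NA  # exclude self
  acc <- vapply(grid, function(sg) {
    logk <- -d2 / (2 * sg^2)
    pred <- vapply(seq_len(n), function(i) {
      ls <- vapply(.pnnLevels, function(cl) {
        cols <- which(y == cl & seq_len(n) != i)
        if (!length(cols)) return(-Inf)  # class vanishes when i is held out
        w <- if (priors == "uniform") -log(length(cols)) else -log(n - 1)
        logSumExp(logk[i, cols]) + w
      }, numeric(1))
      if (any(!is.finite(ls))) return(NA_character_)
      if (ls["malign"] > ls["benign"]) "malign" else "benign"
    }, character(1))
    ok <- !is.na(pred)
    if (!any(ok)) return(0)
    mean(pred[ok] == as.character(y)[ok])
  }, numeric(1))
  names(acc) <- signif(grid, 4)
  list(sigma = grid[which.max(acc)], accuracy = acc)
}
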