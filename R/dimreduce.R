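# PCA feature reduction with the class-size component rule.

#' Component count by the class-size rule
#'
#' The number of retained components is at most one-third of the number of
#' training patterns in the smaller class: `floor((minClassSize *
#' splitFraction) / 3)`, with a floor of 1.  With the reference dataset —
#' smallest class 104 patterns and a half split — the rule yields 17.
#'
#' @param minClassSize size of the smaller class (>= 3).
#' @param splitFraction fraction of the data used for training (0, 1\].
#' @return integer component count >= 1.
#' @examples
#' nComponentsRule(104, 0.5)  # 17
#' @export
nComponentsRule <- function(minClassSize, splitFraction = 0.5) {
  if (minClassSize < 3) stop("minClassSize must be >= 3", call. = FALSE)
  if (splitFraction <= 0 || splitFraction > 1)
    stop("splitFraction must be in (0, 1]", call. = FALSE)
  max(1L, as.integer(floor(minClassSize * splitFraction / 3)))
}

#' Fit a standardized PCA model
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns pass through with scale 1), components are the top eigenvectors
#' of the correlation structure ordered by explained variance, and each
#' loading's sign is fixed so its largest-magnitude entry is positive —
#' making the fit fully deterministic.
#'
#' @param X numeric matrix or data.frame, one feature vector per row
#'   (rows >= nComponents + 1, no missing values).
#' @param nComponents components to retain (<= rank of the standardized
#'   data).
#' @return A [PCAModel-class].
#' @export
pcaFit <- function(X, nComponents) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  nComponents <- as.integer(nComponents)
  if (nrow(X) < nComponents + 1L)
    stop("need at least nComponents + 1 rows", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  scales <- ifelse(sds < 1e-12, 1, sds)
  Xs <- sweep(sweep(X, 2, means), 2, scales, "/")
  sv <- svd(Xs)
  ev <- sv$d^2 / max(1, nrow(X) - 1)
  rank <- sum(sv$d > max(dim(Xs)) * .Machine$double.eps * sv$d[1])
  if (nComponents > rank)
    stop("nComponents = ", nComponents, " exceeds the data rank ", rank,
         call. = FALSE)
  load <- sv$v[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(ncol(load))) {
    imax <- which.max(abs(load[, k]))
    if (load[imax, k] < 0) load[, k] <- -load[, k]
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  rownames(load) <- fn
  colnames(load) <- paste0("PC", seq_len(nComponents))
  new("PCAModel", means = means, scales = scales, loadings = load,
      explainedVariance = ev, nComponents = nComponents, featureNames = fn)
}

#' Project data onto a fitted PCA model
#'
#' Standardizes with the training means/scales and projects onto the
#' retained components.
#'
#' @param model a [PCAModel-class].
#' @param X matrix or data.frame with the same columns as the fit.
#' @return numeric matrix, `nrow(X)` x `nComponents`.
#' @export
pcaTransform <- function(model, X) {
  stopifnot(is(model, "PCAModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@means))
    stop("column count does not match the fitted model", call. = FALSE)
  if (!is.null(colnames(X)) && !identical(colnames(X), model@featureNames))
    stop("column names do not match the fitted model", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model@means), 2, model@scales, "/")
  Xs %*% model@loadings
}

#' Explained variance accessor
#'
#' @param model a [PCAModel-class].
#' @return numeric vector of per-component variances (all components of the
#'   fit, nonincreasing).
#' @export
explainedVariance <- function(model) {
  stopifnot(is(model, "PCAModel"))
  model@explainedVariance
}
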