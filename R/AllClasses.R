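#' CTSlice: a single gray-level CT image
#'
#' The unit of processing in the pipeline: one 2D gray-level raster with
#' intensities normalized to the unit interval, an isotropic physical pixel
#' spacing in millimetres, and an opaque slice identifier.  All pipeline
#' stages operate per slice.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @slot spacingMM physical edge length of one pixel in millimetres (> 0).
#' @slot sliceId opaque identifier string.
#'
#' @name CTSlice-class
#' @aliases CTSlice-class
#' @exportClass CTSlice
setClass("CTSlice",
         representation(pixels = "matrix", spacingMM = "numeric",
                        sliceId = "character"),
         validity = function(object) {
           p <- object@pixels
           if (!is.numeric(p)) return("pixels must be numeric")
           if (nrow(p) < 32 || ncol(p) < 32)
             return("CT slices must be at least 32x32 pixels")
           if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
           if (min(p) < 0 || max(p) > 1) return("pixels must lie in [0, 1]")
           if (length(object@spacingMM) != 1L || object@spacingMM <= 0)
             return("spacingMM must be a single positive number")
           if (length(object@sliceId) != 1L)
             return("sliceId must be a single string")
           TRUE
         })

#' Construct a CTSlice
#'
#' @param pixels numeric matrix with values in \[0, 1\] (at least 32x32).
#' @param spacingMM isotropic physical pixel spacing in millimetres.
#' @param sliceId identifier carried through the pipeline.
#' @return A [CTSlice-class] object.
#' @examples
#' sl <- CTSlice(matrix(runif(64 * 64), 64), spacingMM = 0.7, sliceId = "demo")
#' dim(pixels(sl))
#' @export
CTSlice <- function(pixels, spacingMM = 0.7, sliceId = "slice") {
  new("CTSlice", pixels = pixels, spacingMM = as.numeric(spacingMM),
      sliceId = as.character(sliceId))
}

#' @describeIn CTSlice Pixel matrix accessor.
#' @param x a `CTSlice`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname CTSlice
#' @export
setMethod("pixels", "CTSlice", function(x) x@pixels)

#' @describeIn CTSlice Physical pixel spacing (mm) accessor.
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname CTSlice
#' @export
setMethod("pixelSpacing", "CTSlice", function(x) x@spacingMM)

#' @describeIn CTSlice Slice identifier accessor.
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))

#' @rdname CTSlice
#' @export
setMethod("sliceId", "CTSlice", function(x) x@sliceId)

setMethod("dim", "CTSlice", function(x) dim(x@pixels))

setMethod("show", "CTSlice", function(object) {
  cat(sprintf("CTSlice '%s': %d x %d px, spacing %.3g mm, range [%.3f, %.3f]\n",
              object@sliceId, nrow(object@pixels), ncol(object@pixels),
              object@spacingMM, min(object@pixels), max(object@pixels)))
})

#' SOMModel: trained self-organizing map
#'
#' Prototype vectors of a 1D-chain self-organizing map, one row per node,
#' together with the configuration used for training.
#'
#' @slot weights numeric matrix, one prototype vector per row.
#' @slot config the `somConfig()` list used for training.
#' @name SOMModel-class
#' @exportClass SOMModel
setClass("SOMModel",
         representation(weights = "matrix", config = "list"),
         validity = function(object) {
           if (anyNA(object@weights) || any(!is.finite(object@weights)))
             return("weights must be finite")
           if (nrow(object@weights) != object@config$nNodes)
             return("node count must equal config$nNodes")
           TRUE
         })

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d nodes (1D chain), %d-dim features, %d epochs\n",
              nrow(object@weights), ncol(object@weights),
              object@config$epochs))
})

#' PCAModel: standardized principal component model
#'
#' Per-feature standardization (means and scales) plus the retained
#' orthonormal component loadings and their explained variances.
#'
#' @slot means,scales per-feature standardization parameters.
#' @slot loadings p x k orthonormal loading matrix.
#' @slot explainedVariance variance per retained component, nonincreasing.
#' @slot nComponents retained component count.
#' @slot featureNames column names the model was fitted on.
#' @name PCAModel-class
#' @exportClass PCAModel
setClass("PCAModel",
         representation(means = "numeric", scales = "numeric",
                        loadings = "matrix", explainedVariance = "numeric",
                        nComponents = "integer", featureNames = "character"),
         validity = function(object) {
           if (object@nComponents != ncol(object@loadings))
             return("nComponents must match loadings")
           ev <- object@explainedVariance
           if (is.unsorted(rev(ev), strictly = FALSE) && length(ev) > 1)
             return("explainedVariance must be nonincreasing")
           TRUE
         })

setMethod("show", "PCAModel", function(object) {
  tot <- sum(object@explainedVariance)
  k <- object@nComponents
  cum <- if (tot > 0) sum(object@explainedVariance[seq_len(k)]) / tot else NA
  cat(sprintf("PCAModel: %d features -> %d components (%.1f%% variance)\n",
              length(object@means), k, 100 * cum))
})

#' PNNModel: probabilistic neural network
#'
#' A Parzen-window classifier: the pattern layer stores every training
#' vector verbatim; class scores are Gaussian-kernel averages.
#'
#' @slot patterns training vectors, one row per pattern unit.
#' @slot labels factor of class labels (`benign` / `malign`) per pattern.
#' @slot sigma Gaussian spread (> 0).
#' @slot priors `"uniform"` (class-mean kernels) or `"proportional"`.
#' @name PNNModel-class
#' @exportClass PNNModel
setClass("PNNModel",
         representation(patterns = "matrix", labels = "factor",
                        sigma = "numeric", priors = "character"),
         validity = function(object) {
           if (object@sigma <= 0) return("sigma must be positive")
           if (nrow(object@patterns) != length(object@labels))
             return("one label per pattern required")
           if (!all(levels(object@labels) == c("benign", "malign")))
             return("labels must use levels benign/malign")
           if (any(table(object@labels) < 1))
             return("at least one pattern per class required")
           TRUE
         })

setMethod("show", "PNNModel", function(object) {
  tb <- table(object@labels)
  cat(sprintf("PNNModel: %d pattern units (%d benign, %d malign), sigma = %.4g, priors = %s\n",
              nrow(object@patterns), tb[["benign"]], tb[["malign"]],
              object@sigma, object@priors))
})

#' ConfusionMatrix: binary confusion counts
#'
#' Counts for the two-class problem with `malign` as the positive class:
#' TP = malign predicted malign, TN = benign predicted benign,
#' FP = benign predicted malign, FN = malign predicted benign.
#'
#' @slot TP,FP,FN,TN nonnegative integer counts.
#' @name ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
         representation(TP = "integer", FP = "integer", FN = "integer",
                        TN = "integer"),
         validity = function(object) {
           v <- c(object@TP, object@FP, object@FN, object@TN)
           if (any(v < 0)) return("counts must be nonnegative")
           TRUE
         })

#' Construct a ConfusionMatrix from counts
#'
#' @param TP,FP,FN,TN nonnegative counts; positive class is `malign`.
#' @return A [ConfusionMatrix-class] object.
#' @examples
#' cm <- ConfusionMatrix(113, 6, 3, 98)
#' performanceMetrics(cm)
#' @export
ConfusionMatrix <- function(TP, FP, FN, TN) {
  new("ConfusionMatrix", TP = as.integer(TP), FP = as.integer(FP),
      FN = as.integer(FN), TN = as.integer(TN))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (positive = malign): TP=%d FP=%d FN=%d TN=%d\n",
              object@TP, object@FP, object@FN, object@TN))
})
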