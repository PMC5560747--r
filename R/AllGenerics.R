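#' Accessors for kronDTI objects
#'
#' Small accessor family in place of direct slot access: axis identifiers,
#' affinity values, the observed mask, kernel entries and the normalization
#' flag.
#'
#' @param x a [BioactivityMatrix-class], [KernelMatrix-class] or
#'   [KronRLSModel-class] object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("affinityValues", function(x) standardGeneric("affinityValues"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("kernelIds", function(x) standardGeneric("kernelIds"))
#' @rdname accessors
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setMethod("drugIds", "BioactivityMatrix", function(x) x@drugIds)
#' @rdname accessors
#' @export
setMethod("proteinIds", "BioactivityMatrix", function(x) x@proteinIds)
#' @rdname accessors
#' @export
setMethod("affinityValues", "BioactivityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("observedMask", "BioactivityMatrix", function(x) x@observed)
#' @rdname accessors
#' @export
setMethod("drugIds", "KronRLSModel", function(x) x@drugIds)
#' @rdname accessors
#' @export
setMethod("proteinIds", "KronRLSModel", function(x) x@proteinIds)
#' @rdname accessors
#' @export
setMethod("kernelIds", "KernelMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("kernelValues", "KernelMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("isNormalized", "KernelMatrix", function(x) x@normalized)

setMethod("show", "BioactivityMatrix", function(object) {
  cat(sprintf("BioactivityMatrix: %d drugs x %d proteins, %d/%d observed (%.1f%%)\n",
              length(object@drugIds), length(object@proteinIds),
              sum(object@observed), length(object@observed),
              100 * mean(object@observed)))
  v <- object@values[object@observed]
  if (length(v))
    cat(sprintf("  pKi range [%.2f, %.2f], mean %.2f\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d%s\n", length(object@ids),
              length(object@ids),
              if (object@normalized) ", cosine-normalized" else ""))
})

setMethod("show", "KronRLSModel", function(object) {
  cat(sprintf("KronRLSModel: %d drugs x %d proteins, lambda = %g\n",
              length(object@drugIds), length(object@proteinIds),
              object@lambda))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: %d outer folds, Pearson r = %.3f, RMSE = %.3f\n",
              object@scenario, nrow(object@selected), object@pearson,
              object@rmse))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: n = %d, r = %.3f, RMSE = %.3f, mean AUC = %.3f (%d thresholds",
              object@n, object@pearsonR, object@rmse, object@meanAuc,
              length(object@aucByThreshold)))
  if (length(object@skippedThresholds))
    cat(sprintf(", %d skipped", length(object@skippedThresholds)))
  cat(")\n")
})

#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))
#' @rdname accessors
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)
#' @rdname accessors
#' @export
setGeneric("cvSelected", function(x) standardGeneric("cvSelected"))
#' @rdname accessors
#' @export
setMethod("cvSelected", "CVResult", function(x) x@selected)
#' @rdname accessors
#' @export
setGeneric("cvPearson", function(x) standardGeneric("cvPearson"))
#' @rdname accessors
#' @export
setMethod("cvPearson", "CVResult", function(x) x@pearson)
#' @rdname accessors
#' @export
setGeneric("cvRmse", function(x) standardGeneric("cvRmse"))
#' @rdname accessors
#' @export
setMethod("cvRmse", "CVResult", function(x) x@rmse)
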