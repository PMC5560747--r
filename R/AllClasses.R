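#' @import methods
#' @importFrom stats cor quantile rnorm runif rbinom dist phyper setNames predict fitted
#' @importFrom utils read.table write.table
NULL

.sym_tol <- 1e-10
.psd_tol <- 1e-8

#' Labeled sparse compound-by-protein bioactivity matrix
#'
#' Container for a quantitative drug-target interaction map: a real-valued
#' matrix of binding affinities on the pKi scale (-log10 of the molar
#' inhibition constant Ki) with drugs in rows and protein targets in columns,
#' together with a logical mask marking which cells were actually measured.
#' Unmeasured cells carry \code{NA} in \code{values} until imputation.
#'
#' @slot drugIds character vector of unique compound identifiers (rows).
#' @slot proteinIds character vector of unique protein identifiers (columns).
#' @slot values numeric matrix, \code{length(drugIds)} x
#'   \code{length(proteinIds)}, pKi units.
#' @slot observed logical matrix of the same shape; \code{TRUE} marks a
#'   measured cell. Every observed cell must hold a finite value.
#'
#' @seealso [bioactivityMatrix()], [readBioactivityMatrix()], [imputeMissing()]
#' @export
setClass("BioactivityMatrix",
  slots = c(
    drugIds = "character",
    proteinIds = "character",
    values = "matrix",
    observed = "matrix"
  )
)

setValidity("BioactivityMatrix", function(object) {
  msg <- character()
  nD <- length(object@drugIds)
  nP <- length(object@proteinIds)
  if (anyDuplicated(object@drugIds))
    msg <- c(msg, sprintf("duplicate drug id: '%s'",
                          object@drugIds[duplicated(object@drugIds)][1L]))
  if (anyDuplicated(object@proteinIds))
    msg <- c(msg, sprintf("duplicate protein id: '%s'",
                          object@proteinIds[duplicated(object@proteinIds)][1L]))
  if (!is.numeric(object@values) || !identical(dim(object@values), c(nD, nP)))
    msg <- c(msg, "'values' must be a numeric drugs x proteins matrix")
  if (!is.logical(object@observed) || !identical(dim(object@observed), dim(object@values)))
    msg <- c(msg, "'observed' must be a logical matrix matching 'values'")
  else if (any(object@observed & !is.finite(object@values)))
    msg <- c(msg, "observed cells must hold finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a BioactivityMatrix
#'
#' @param values numeric drugs x proteins matrix; \code{NA} marks missing
#'   cells unless \code{observed} is given explicitly.
#' @param drugIds,proteinIds identifiers; default to dimnames of
#'   \code{values}.
#' @param observed optional logical mask; defaults to \code{!is.na(values)}.
#' @return A [BioactivityMatrix-class] object.
#' @examples
#' Y <- matrix(c(5, NA, 7, 6), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("p1", "p2")))
#' bioactivityMatrix(Y)
#' @export
bioactivityMatrix <- function(values, drugIds = rownames(values),
                              proteinIds = colnames(values),
                              observed = !is.na(values)) {
  if (is.null(drugIds)) drugIds <- paste0("d", seq_len(nrow(values)))
  if (is.null(proteinIds)) proteinIds <- paste0("p", seq_len(ncol(values)))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(drugIds, proteinIds)
  dimnames(observed) <- dimnames(values)
  new("BioactivityMatrix", drugIds = as.character(drugIds),
      proteinIds = as.character(proteinIds), values = values,
      observed = observed)
}

#' Labeled symmetric positive semidefinite kernel matrix
#'
#' A similarity (kernel) matrix over one axis of the prediction problem,
#' either drugs or proteins. Validity enforces symmetry to 1e-10, positive
#' semidefiniteness up to a relative floor of 1e-8 times the largest
#' eigenvalue, and -- when \code{normalized} is \code{TRUE} -- a unit
#' diagonal to 1e-10.
#'
#' @slot ids character labels of the axis.
#' @slot values square symmetric numeric matrix.
#' @slot normalized logical; \code{TRUE} when cosine-normalized.
#' @seealso [kernelMatrix()], [cosineNormalizeKernel()]
#' @export
setClass("KernelMatrix",
  slots = c(ids = "character", values = "matrix", normalized = "logical")
)

setValidity("KernelMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  K <- object@values
  if (!identical(dim(K), c(n, n)))
    msg <- c(msg, "'values' must be square with one row per id")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate kernel ids")
  if (!all(is.finite(K))) {
    msg <- c(msg, "kernel entries must be finite")
  } else {
    if (max(abs(K - t(K))) > .sym_tol)
      msg <- c(msg, sprintf("kernel not symmetric to tolerance %g", .sym_tol))
    ev <- eigen(0.5 * (K + t(K)), symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(ev, 0)
    if (min(ev) < -.psd_tol * max(lmax, 1))
      msg <- c(msg, "kernel not positive semidefinite to tolerance")
    if (isTRUE(object@normalized) && max(abs(diag(K) - 1)) > .sym_tol)
      msg <- c(msg, "normalized kernel must have unit diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KernelMatrix
#'
#' Symmetrizes minor numerical asymmetry and, if requested, repairs small
#' negative eigenvalues (below \code{-1e-8 * lambda_max}) by clipping them to
#' zero and reconstructing, with a warning.
#'
#' @param values square numeric matrix.
#' @param ids labels; default rownames.
#' @param normalized logical flag recorded on the object.
#' @param repair clip tiny negative eigenvalues before validity checking.
#' @return A [KernelMatrix-class] object.
#' @export
kernelMatrix <- function(values, ids = rownames(values), normalized = FALSE,
                         repair = TRUE) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(values)))
  K <- 0.5 * (values + t(values))
  if (repair) {
    e <- eigen(K, symmetric = TRUE)
    lmax <- max(e$values, 0)
    if (min(e$values) < -.psd_tol * max(lmax, 1)) {
      warning("clipping negative kernel eigenvalues to zero (PSD repair)")
      v <- pmax(e$values, 0)
      K <- e$vectors %*% (v * t(e$vectors))
      K <- 0.5 * (K + t(K))
      if (normalized) {
        d <- sqrt(pmax(diag(K), 0))
        d[d == 0] <- 1
        K <- K / outer(d, d)
        diag(K) <- 1
      }
    }
  }
  dimnames(K) <- list(ids, ids)
  new("KernelMatrix", ids = as.character(ids), values = K,
      normalized = normalized)
}

#' Fitted KronRLS model
#'
#' Holds the eigendecompositions of the drug and protein kernels, the
#' regularization parameter and the dual coefficient matrix C (proteins x
#' drugs), from which the dual vector is \code{vec(U_P C t(U_D))} in
#' column-major order with the protein index varying fastest.
#'
#' @slot lambda positive regularization parameter.
#' @slot drugEigvecs,proteinEigvecs orthogonal eigenvector matrices of the
#'   training kernels.
#' @slot drugEigvals,proteinEigvals eigenvalues (clipped at zero from below
#'   when within numerical tolerance of zero).
#' @slot dual the C matrix, proteins x drugs.
#' @slot drugKernel,proteinKernel training kernel matrices (kept for fitted
#'   values and training-point prediction).
#' @slot drugIds,proteinIds training axis labels.
#' @export
setClass("KronRLSModel",
  slots = c(
    lambda = "numeric",
    drugEigvecs = "matrix", drugEigvals = "numeric",
    proteinEigvecs = "matrix", proteinEigvals = "numeric",
    dual = "matrix",
    drugKernel = "matrix", proteinKernel = "matrix",
    drugIds = "character", proteinIds = "character"
  )
)

setValidity("KronRLSModel", function(object) {
  msg <- character()
  if (length(object@lambda) != 1L || object@lambda <= 0)
    msg <- c(msg, "'lambda' must be a single positive value")
  for (side in c("drug", "protein")) {
    U <- slot(object, paste0(side, "Eigvecs"))
    if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8)
      msg <- c(msg, sprintf("%s eigenvector matrix not orthogonal", side))
  }
  if (!identical(dim(object@dual),
                 c(length(object@proteinIds), length(object@drugIds))))
    msg <- c(msg, "'dual' must be proteins x drugs")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' Per-fold out-of-sample predictions with observed values, the grid point
#' selected in each outer fold, and aggregate accuracy.
#'
#' @slot scenario one of "bioactivity_imputation", "new_drug", "new_target".
#' @slot predictions data.frame with columns drug_id, protein_id, measured,
#'   predicted, fold.
#' @slot selected data.frame of selected grid parameters per outer fold.
#' @slot pearson,rmse aggregate accuracy over all outer predictions.
#' @slot seed integer seed the plan was built from.
#' @export
setClass("CVResult",
  slots = c(
    scenario = "character",
    predictions = "data.frame",
    selected = "data.frame",
    pearson = "numeric",
    rmse = "numeric",
    seed = "integer"
  )
)

#' Evaluation report for predicted-vs-measured affinities
#'
#' @slot pearsonR Pearson correlation between measured and predicted values.
#' @slot rmse root mean squared error.
#' @slot aucByThreshold named numeric vector, ROC-AUC per binarization
#'   threshold (names are the thresholds); degenerate thresholds omitted.
#' @slot meanAuc mean over the valid thresholds.
#' @slot skippedThresholds thresholds with a single class, excluded from the
#'   mean.
#' @slot n number of pairs scored.
#' @export
setClass("EvaluationReport",
  slots = c(
    pearsonR = "numeric", rmse = "numeric",
    aucByThreshold = "numeric", meanAuc = "numeric",
    skippedThresholds = "numeric", n = "integer"
  )
)
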