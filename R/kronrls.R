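#' Similarity-weighted imputation of missing bioactivities
#'
#' The eigendecomposition shortcut of KronRLS requires a complete label
#' matrix, so missing affinities are filled in beforehand by the weighted row
#' (compound) average: for a missing cell (i, j) the imputed value is
#' \deqn{\hat y_{ij} = \sum_k s(j,k)\, y_{ik} \Big/ \sum_k s(j,k)}
#' over the observed proteins k in row i, with weights given by
#' protein-protein similarity (typically normalized Smith-Waterman scores).
#' Imputed cells keep \code{observed = FALSE} so they can be discarded when
#' assessing predictive performance.
#'
#' Fallback chain for degenerate cases: all weights zero -> unweighted row
#' mean; row fully missing -> observed column mean -> global mean of all
#' observed entries.
#'
#' @param Y a [BioactivityMatrix-class].
#' @param proteinSimilarity square similarity matrix over \code{proteinIds(Y)}
#'   (matching order), e.g. from [normalizedSWMatrix()].
#' @return A [BioactivityMatrix-class] with complete \code{values} and the
#'   original \code{observed} mask.
#' @export
imputeMissing <- function(Y, proteinSimilarity) {
  vals <- affinityValues(Y)
  obs <- observedMask(Y)
  nP <- ncol(vals)
  S <- as.matrix(proteinSimilarity)
  if (!identical(dim(S), c(nP, nP)))
    stop("protein similarity must be square over the protein axis")
  if (all(obs)) return(Y)
  globalMean <- if (any(obs)) mean(vals[obs]) else NA_real_
  colMeans_ <- vapply(seq_len(nP), function(j) {
    o <- obs[, j]
    if (any(o)) mean(vals[o, j]) else NA_real_
  }, numeric(1L))
  out <- vals
  for (i in seq_len(nrow(vals))) {
    oi <- obs[i, ]
    mi <- which(!oi)
    if (!length(mi)) next
    if (!any(oi)) {
      fill <- colMeans_[mi]
      fill[is.na(fill)] <- globalMean
      out[i, mi] <- fill
      next
    }
    yobs <- vals[i, oi]
    W <- S[mi, oi, drop = FALSE]
    wsum <- rowSums(W)
    v <- as.vector(W %*% yobs) / wsum
    zero <- wsum <= 0
    if (any(zero)) v[zero] <- mean(yobs)
    out[i, mi] <- v
  }
  if (anyNA(out)) stop("imputation failed: no observed entries at all")
  bioactivityMatrix(out, drugIds(Y), proteinIds(Y), observed = obs)
}

# shared orientation convention: Y is drugs x proteins; the dual vector
# stacks the columns of the proteins x drugs matrix A = U_P C t(U_D), i.e.
# pair (drug i, protein j) sits at vec index (i-1)*nP + j, matching
# kronecker(K_D, K_P).
.vec_pair_index <- function(i, j, nP) (i - 1L) * nP + j

#' Explicit KronRLS solve (reference path)
#'
#' Materializes the pairwise Kronecker kernel \eqn{K = K_D \otimes K_P} and
#' solves \eqn{(K + \lambda I)\alpha = y} with a dense linear solve. This is
#' the small-scale reference implementation used to validate the fast
#' eigendecomposition path; it refuses problems above 4096 drug-protein
#' pairs.
#'
#' @param KD,KP kernel matrices ([KernelMatrix-class] or plain symmetric
#'   matrices) for drugs and proteins.
#' @param Y complete numeric drugs x proteins matrix (or
#'   [BioactivityMatrix-class] with all cells observed).
#' @param lambda regularization, > 0.
#' @return list with \code{alpha} (dual vector, protein index fastest) and
#'   \code{fitted} (drugs x proteins matrix of training predictions).
#' @export
kronrlsSolveExplicit <- function(KD, KP, Y, lambda) {
  KD <- .kernel_values(KD)
  KP <- .kernel_values(KP)
  Ym <- .complete_values(Y)
  nD <- nrow(Ym)
  nP <- ncol(Ym)
  if (nD * nP > 4096)
    stop("explicit solver limited to 4096 pairs; use kronrlsFit()")
  if (lambda <= 0) stop("'lambda' must be positive")
  K <- kronecker(KD, KP)
  y <- as.vector(t(Ym))          # vec of t(Y): protein index fastest
  alpha <- solve(K + lambda * diag(nD * nP), y)
  fitted <- t(matrix(K %*% alpha, nP, nD))
  dimnames(fitted) <- dimnames(Ym)
  list(alpha = alpha, fitted = fitted)
}

#' Fit a KronRLS model via kernel eigendecompositions
#'
#' The fast training path: eigendecompose the drug and protein kernels,
#' \eqn{K_D = U_D \Sigma_D U_D^T}, \eqn{K_P = U_P \Sigma_P U_P^T}, form
#' \deqn{C = (U_P^T Y^T U_D) \oslash (\sigma_P \sigma_D^T + \lambda)}
#' (elementwise division), and the dual vector is \eqn{vec(U_P C U_D^T)}.
#' Training predictions and new-pair predictions never materialize the
#' Kronecker kernel. Eigenvalues within numerical tolerance below zero are
#' clipped to zero.
#'
#' @inheritParams kronrlsSolveExplicit
#' @return A [KronRLSModel-class].
#' @seealso [kronrlsSolveExplicit()] for the reference path,
#'   [predict,KronRLSModel-method] for out-of-sample prediction.
#' @export
kronrlsFit <- function(KD, KP, Y, lambda) {
  if (length(lambda) != 1L || lambda <= 0) stop("'lambda' must be positive")
  dIds <- .axis_ids(KD, Y, 1L)
  pIds <- .axis_ids(KP, Y, 2L)
  KDm <- .kernel_values(KD)
  KPm <- .kernel_values(KP)
  Ym <- .complete_values(Y)
  eD <- eigen(KDm, symmetric = TRUE)
  eP <- eigen(KPm, symmetric = TRUE)
  sD <- .clip_eigvals(eD$values)
  sP <- .clip_eigvals(eP$values)
  M <- crossprod(eP$vectors, t(Ym)) %*% eD$vectors   # U_P' Y' U_D
  C <- M / (outer(sP, sD) + lambda)
  new("KronRLSModel", lambda = lambda,
      drugEigvecs = eD$vectors, drugEigvals = sD,
      proteinEigvecs = eP$vectors, proteinEigvals = sP,
      dual = C, drugKernel = KDm, proteinKernel = KPm,
      drugIds = dIds, proteinIds = pIds)
}

.clip_eigvals <- function(v) {
  lmax <- max(v, 0)
  floor_ <- -.psd_tol * max(lmax, 1)
  if (min(v) < floor_)
    warning("kernel has eigenvalues below the PSD tolerance; clipping")
  pmax(v, 0)
}

# A = U_P C t(U_D), proteins x drugs; prediction f(kD, kP) = kP A t(kD)
.model_A <- function(model) {
  model@proteinEigvecs %*% model@dual %*% t(model@drugEigvecs)
}

#' Training-grid predictions of a KronRLS model
#'
#' @param object a [KronRLSModel-class].
#' @param ... ignored.
#' @return drugs x proteins matrix of fitted affinities.
#' @export
setMethod("fitted", "KronRLSModel", function(object, ...) {
  A <- .model_A(object)
  F <- t(object@proteinKernel %*% A %*% object@drugKernel)
  dimnames(F) <- list(object@drugIds, object@proteinIds)
  F
})

#' Predict binding affinities for query kernel vectors
#'
#' Evaluates \eqn{f(x) = k_P (U_P C U_D^T) k_D^T} for query drugs and
#' proteins described by their kernel similarities to the training axes.
#'
#' @param object a [KronRLSModel-class].
#' @param kD numeric vector of similarities of the query drug to the
#'   training drugs, or a matrix with one query drug per row.
#' @param kP likewise for the query protein(s); defaults to the training
#'   protein kernel (predict against all training proteins).
#' @param ... ignored.
#' @return matrix of predictions, query drugs x query proteins (dropped to a
#'   scalar for single vectors).
#' @export
setMethod("predict", "KronRLSModel", function(object, kD,
                                              kP = object@proteinKernel,
                                              ...) {
  kD <- .query_matrix(kD, length(object@drugIds), "kD")
  kP <- .query_matrix(kP, length(object@proteinIds), "kP")
  A <- .model_A(object)
  out <- kD %*% t(A) %*% t(kP)    # queries_D x queries_P
  if (nrow(out) == 1L && ncol(out) == 1L) drop(out) else out
})

#' Dual coefficient vector of a fitted model
#'
#' Returns \eqn{\alpha = vec(U_P C U_D^T)} in the package's fixed
#' orientation (protein index varying fastest within each drug), matching
#' the explicit solver's ordering.
#'
#' @param model a [KronRLSModel-class].
#' @return numeric vector of length nDrugs * nProteins.
#' @export
dualVector <- function(model) {
  as.vector(.model_A(model))
}

#' Diagonal of the KronRLS hat matrix
#'
#' The smoother diagonal \eqn{h_{ij}} of \eqn{H = K(K+\lambda I)^{-1}} in
#' the Kronecker eigenbasis, as a drugs x proteins matrix. Used for exact
#' closed-form leave-one-entry-out model selection: replacing a training
#' label \eqn{y_c} by \eqn{y^*} changes the fitted value at c by
#' \eqn{h_c (y^* - y_c)}.
#'
#' @param model a [KronRLSModel-class].
#' @return drugs x proteins matrix of leverage values in [0, 1].
#' @export
hatDiagonal <- function(model) {
  W <- outer(model@drugEigvals, model@proteinEigvals) /
    (outer(model@drugEigvals, model@proteinEigvals) + model@lambda)
  H <- (model@drugEigvecs^2) %*% W %*% t(model@proteinEigvecs^2)
  dimnames(H) <- list(model@drugIds, model@proteinIds)
  H
}

.kernel_values <- function(K) {
  if (is(K, "KernelMatrix")) kernelValues(K) else as.matrix(K)
}

.axis_ids <- function(K, Y, margin) {
  if (is(K, "KernelMatrix")) return(kernelIds(K))
  if (is(Y, "BioactivityMatrix"))
    return(if (margin == 1L) drugIds(Y) else proteinIds(Y))
  ids <- dimnames(as.matrix(Y))[[margin]]
  if (is.null(ids)) ids <- paste0(c("d", "p")[margin], seq_len(dim(as.matrix(Y))[margin]))
  ids
}

.complete_values <- function(Y) {
  if (is(Y, "BioactivityMatrix")) {
    if (anyNA(affinityValues(Y)))
      stop("label matrix has missing entries; run imputeMissing() first")
    return(affinityValues(Y))
  }
  Ym <- as.matrix(Y)
  if (anyNA(Ym))
    stop("label matrix has missing entries; run imputeMissing() first")
  Ym
}

.query_matrix <- function(k, n, what) {
  if (is.null(dim(k))) k <- matrix(k, nrow = 1L)
  k <- as.matrix(k)
  if (ncol(k) != n)
    stop(sprintf("'%s' must have %d columns (training axis size)", what, n))
  k
}
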