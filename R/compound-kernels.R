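#' Tanimoto similarity between two binary fingerprints
#'
#' Jaccard-type score on substructure bit vectors:
#' \deqn{S(i,j) = N_{11} / (N_i + N_j - N_{11})}
#' where \eqn{N_i} counts 1-bits of fingerprint i and \eqn{N_{11}} the bits
#' set in both. Two all-zero fingerprints score 1 (identity of
#' indiscernibles); an all-zero vector against a non-empty one scores 0.
#'
#' @param fpI,fpJ binary vectors of equal length.
#' @return similarity in [0, 1].
#' @examples
#' tanimotoSimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimotoSimilarity <- function(fpI, fpJ) {
  if (length(fpI) != length(fpJ))
    stop("fingerprint length mismatch: ", length(fpI), " vs ", length(fpJ))
  if (!all(fpI %in% c(0, 1)) || !all(fpJ %in% c(0, 1)))
    stop("fingerprints must be binary")
  n11 <- sum(fpI == 1 & fpJ == 1)
  ni <- sum(fpI)
  nj <- sum(fpJ)
  if (ni + nj == 0) return(1)
  n11 / (ni + nj - n11)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param bits binary matrix, one fingerprint per row; rownames are the
#'   compound identifiers.
#' @return square similarity matrix with entries in [0, 1].
#' @export
tanimotoMatrix <- function(bits) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0, 1))) stop("fingerprints must be binary")
  storage.mode(bits) <- "double"
  n11 <- tcrossprod(bits)
  counts <- rowSums(bits)
  denom <- outer(counts, counts, "+") - n11
  S <- ifelse(denom == 0, 1, n11 / denom)
  # empty-vs-non-empty pairs have denom > 0 and n11 = 0 -> 0, as intended
  dimnames(S) <- list(rownames(bits), rownames(bits))
  S
}

#' Cosine-normalize a kernel matrix
#'
#' \eqn{K'(i,j) = K(i,j) / \sqrt{K(i,i) K(j,j)}}, the standard normalization
#' giving a unit diagonal. Degenerate rows with a zero diagonal entry map to
#' 1 on the diagonal and 0 off-diagonal.
#'
#' @param K square numeric matrix.
#' @return normalized matrix.
#' @export
cosineNormalizeKernel <- function(K) {
  d <- diag(K)
  if (any(d < 0)) stop("negative diagonal entry; not a kernel")
  zero <- d == 0
  s <- sqrt(ifelse(zero, 1, d))
  Kn <- K / outer(s, s)
  if (any(zero)) {
    Kn[zero, ] <- 0
    Kn[, zero] <- 0
  }
  diag(Kn) <- 1
  Kn
}

#' Linear kernel from a similarity (feature) matrix
#'
#' Forms \eqn{K = S S^T} over the rows of S -- the construction used both
#' for fingerprint Tanimoto profiles and for extended Smith-Waterman (SW+)
#' profiles -- followed by cosine normalization. The result is symmetric and
#' positive semidefinite by construction.
#'
#' @param S numeric matrix (rows are objects, columns are features; need not
#'   be square).
#' @param ids labels; default rownames of S.
#' @param normalize cosine-normalize (default TRUE, matching the convention
#'   that every kernel is normalized before use).
#' @return A [KernelMatrix-class].
#' @export
linearKernel <- function(S, ids = rownames(S), normalize = TRUE) {
  S <- as.matrix(S)
  if (!all(is.finite(S))) stop("similarity matrix must be finite")
  K <- tcrossprod(S)
  if (normalize) K <- cosineNormalizeKernel(K)
  kernelMatrix(K, ids = ids, normalized = normalize)
}

#' Gaussian interaction-profile (GIP) kernel
#'
#' Gaussian kernel on interaction profiles: for profiles \eqn{v_i} (a
#' molecule's vector of binding affinities across the partner axis),
#' \deqn{K(i,j) = \exp(-\|v_i - v_j\|^2 / (2\sigma^2)).}
#' Profiles must be fully observed -- impute the bioactivity matrix first
#' (see [imputeMissing()]). The same form serves drugs (profiles = rows of
#' the affinity matrix) and proteins (profiles = columns).
#'
#' @param profiles numeric matrix, one fully-observed profile per row.
#' @param sigma kernel width, > 0.
#' @param ids labels; default rownames.
#' @return A [KernelMatrix-class] with unit diagonal.
#' @export
gipKernel <- function(profiles, sigma, ids = rownames(profiles)) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive value")
  profiles <- as.matrix(profiles)
  if (anyNA(profiles))
    stop("profiles contain missing values; run imputeMissing() first")
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  kernelMatrix(K, ids = ids, normalized = TRUE, repair = FALSE)
}

#' Candidate Gaussian widths from the pairwise-distance quantile rule
#'
#' Returns the 0.1, 0.5 and 0.9 empirical quantiles (linear interpolation,
#' \code{stats::quantile} type 7) of the off-diagonal pairwise Euclidean
#' distances between profiles, the rule used to build the width grid for
#' interaction-profile kernels. Distances (not squared distances) are used.
#'
#' @param profiles numeric matrix, one profile per row (at least 2 rows).
#' @return numeric vector of three candidate sigma values.
#' @export
sigmaGridFromDistances <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  d <- as.vector(stats::dist(profiles))
  q <- unname(quantile(d, c(0.1, 0.5, 0.9), type = 7))
  if (all(q == 0))
    stop("all profiles identical: candidate sigma values are zero")
  q
}
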