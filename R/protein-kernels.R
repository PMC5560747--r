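#' Alignment parameters for Smith-Waterman scoring
#'
#' Affine gap scheme: a gap of length L costs
#' \code{gapOpen + L * gapExtend}. Defaults are the EMBOSS water defaults
#' for BLOSUM50 (open 10, extend 0.5).
#'
#' @param substitution symmetric substitution matrix; default bundled
#'   BLOSUM50.
#' @param gapOpen,gapExtend non-negative penalties, \code{gapExtend <=
#'   gapOpen}.
#' @return list of class \code{"alignmentParams"}.
#' @export
alignmentParams <- function(substitution = blosum50(), gapOpen = 10,
                            gapExtend = 0.5) {
  stopifnot(gapOpen >= 0, gapExtend >= 0, gapExtend <= gapOpen)
  if (max(abs(substitution - t(substitution))) > 0)
    stop("substitution matrix must be symmetric")
  structure(list(substitution = substitution, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "alignmentParams")
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gaps, computed with
#' [Biostrings::pairwiseAlignment()].
#'
#' @param s1,s2 amino-acid strings (character or AAString).
#' @param params an [alignmentParams()] list.
#' @return non-negative alignment score.
#' @export
smithWatermanScore <- function(s1, s2, params = alignmentParams()) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(s1)),
    Biostrings::AAString(as.character(s2)),
    type = "local",
    substitutionMatrix = params$substitution,
    gapOpening = params$gapOpen,
    gapExtension = params$gapExtend,
    scoreOnly = TRUE)
}

#' Normalized Smith-Waterman similarity
#'
#' \deqn{s(i,j) = SW(i,j) / \sqrt{SW(i,i) \, SW(j,j)}}
#' so that each sequence has similarity exactly 1 with itself.
#'
#' @inheritParams smithWatermanScore
#' @return similarity in (0, 1] for typical substitution matrices.
#' @export
normalizedSWSimilarity <- function(s1, s2, params = alignmentParams()) {
  s11 <- smithWatermanScore(s1, s1, params)
  s22 <- smithWatermanScore(s2, s2, params)
  if (s11 <= 0 || s22 <= 0)
    stop("zero Smith-Waterman self-score; cannot normalize")
  smithWatermanScore(s1, s2, params) / sqrt(s11 * s22)
}

#' Pairwise normalized Smith-Waterman similarity matrix
#'
#' @param seqs named [Biostrings::AAStringSet] or named character vector.
#' @param params an [alignmentParams()] list.
#' @return square similarity matrix with unit diagonal.
#' @export
normalizedSWMatrix <- function(seqs, params = alignmentParams()) {
  seqs <- .as_aa_set(seqs)
  n <- length(seqs)
  self <- vapply(seq_len(n), function(i)
    smithWatermanScore(seqs[[i]], seqs[[i]], params), numeric(1L))
  if (any(self <= 0)) stop("zero Smith-Waterman self-score")
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[(i + 1L):n], seqs[[i]], type = "local",
      substitutionMatrix = params$substitution,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend,
      scoreOnly = TRUE)
    S[i, (i + 1L):n] <- S[(i + 1L):n, i] <-
      sc / sqrt(self[i] * self[(i + 1L):n])
  }
  dimnames(S) <- list(names(seqs), names(seqs))
  S
}

#' Smith-Waterman linear kernel over a sequence set
#'
#' Normalized SW similarity matrix followed by the linear kernel
#' \eqn{K = S S^T} and cosine normalization (the "KP-SW" construction).
#'
#' @inheritParams normalizedSWMatrix
#' @return A [KernelMatrix-class].
#' @export
swKernel <- function(seqs, params = alignmentParams()) {
  linearKernel(normalizedSWMatrix(seqs, params))
}

#' Extended target profiles against a reference proteome (SW+)
#'
#' Features for each target are its normalized Smith-Waterman similarities
#' to a larger, external reference set of proteins (rather than only to the
#' targets in the training data):
#' \deqn{S^+(p_i, h_l) = SW(p_i, h_l)/\sqrt{SW(p_i,p_i)\,SW(h_l,h_l)}.}
#' The downstream "KP-SW+" kernel is [linearKernel()] on the rows of this
#' rectangular profile matrix.
#'
#' @param targets,reference named AAStringSets (or named character vectors);
#'   the reference proteome is user-supplied.
#' @param params an [alignmentParams()] list.
#' @return numeric matrix, targets x reference proteins.
#' @export
swPlusProfiles <- function(targets, reference, params = alignmentParams()) {
  targets <- .as_aa_set(targets)
  reference <- .as_aa_set(reference)
  if (!length(targets) || !length(reference))
    stop("both target and reference sets must be non-empty")
  selfT <- vapply(seq_along(targets), function(i)
    smithWatermanScore(targets[[i]], targets[[i]], params), numeric(1L))
  selfR <- vapply(seq_along(reference), function(l)
    smithWatermanScore(reference[[l]], reference[[l]], params), numeric(1L))
  if (any(selfT <= 0) || any(selfR <= 0))
    stop("zero Smith-Waterman self-score")
  P <- matrix(0, length(targets), length(reference),
              dimnames = list(names(targets), names(reference)))
  for (i in seq_along(targets)) {
    sc <- Biostrings::pairwiseAlignment(
      reference, targets[[i]], type = "local",
      substitutionMatrix = params$substitution,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend,
      scoreOnly = TRUE)
    P[i, ] <- sc / sqrt(selfT[i] * selfR)
  }
  P
}

#' Amino-acid descriptor table from substitution-matrix rows
#'
#' Each residue is described by its row of scores against the 20 standard
#' residues (d = 20), the default descriptor encoding of the generic string
#' kernel. Residues absent from the matrix (and X when \code{zeroX}) get the
#' zero vector, i.e. contribute only through the content Gaussian.
#'
#' @param substitution substitution matrix; default bundled BLOSUM50.
#' @param zeroX force a zero descriptor for X even when the matrix has an X
#'   row (default FALSE: use the matrix row when present).
#' @return numeric matrix, residues x 20 descriptor dimensions.
#' @export
blosumDescriptorTable <- function(substitution = blosum50(), zeroX = FALSE) {
  std <- .aa_standard
  resids <- intersect(rownames(substitution), c(std, "X"))
  tab <- substitution[resids, std, drop = FALSE]
  tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  if (!("X" %in% rownames(tab))) {
    tab <- rbind(tab, X = 0)
  } else if (zeroX) {
    tab["X", ] <- 0
  }
  tab
}

#' Generic string (GS) kernel parameters
#'
#' @param L maximum substring length (>= 1).
#' @param sigmaP positional width (> 0): controls how far two substrings may
#'   be shifted relative to each other and still be compared.
#' @param sigmaC content width (> 0): controls how dissimilar the descriptor
#'   encodings of two substrings may be.
#' @return list of class \code{"gsParams"}.
#' @export
gsParams <- function(L = 2L, sigmaP = 1, sigmaC = 10) {
  stopifnot(L >= 1L, sigmaP > 0, sigmaC > 0)
  structure(list(L = as.integer(L), sigmaP = sigmaP, sigmaC = sigmaC),
            class = "gsParams")
}

#' Generic string kernel between two sequences
#'
#' Compares every substring of s of length l <= L with every equal-length
#' substring of s', weighting each comparison by a positional-shift Gaussian
#' on the 0-based start offsets (i, j) and a content Gaussian on the
#' concatenated per-residue descriptor vectors:
#' \deqn{k(s,s') = \sum_{l=1}^{L} \sum_{i=0}^{|s|-l} \sum_{j=0}^{|s'|-l}
#'   e^{-(i-j)^2/(2\sigma_p^2)}\,
#'   e^{-\|\psi^l(s_{i+1..i+l}) - \psi^l(s'_{j+1..j+l})\|^2/(2\sigma_c^2)}.}
#' Lengths l exceeding a sequence contribute empty sums, so any L is valid.
#' The raw pairwise value is unnormalized; matrices are cosine-normalized by
#' [gsKernelMatrix()].
#'
#' @param s,sPrime amino-acid strings.
#' @param params a [gsParams()] list.
#' @param table descriptor table (residues x d); default BLOSUM50 rows.
#' @return non-negative kernel value, symmetric in (s, s').
#' @export
gsKernel <- function(s, sPrime, params = gsParams(),
                     table = blosumDescriptorTable()) {
  A <- .gs_encode(s, table)
  B <- .gs_encode(sPrime, table)
  n <- nrow(A)
  m <- nrow(B)
  # D1[i, j] = squared descriptor distance between residue i of s and j of s'
  D1 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D1[D1 < 0] <- 0
  P <- exp(-outer(seq_len(n) - 1L, seq_len(m) - 1L, "-")^2 /
             (2 * params$sigmaP^2))
  total <- 0
  Dl <- D1
  for (l in seq_len(params$L)) {
    if (l > 1L) {
      nl <- n - l + 1L
      ml <- m - l + 1L
      if (nl < 1L || ml < 1L) break
      # distance of length-l substrings = length-(l-1) distance at the same
      # start + residue distance at the new final position
      Dl <- Dl[seq_len(nl), seq_len(ml), drop = FALSE] +
        D1[seq.int(l, n), seq.int(l, m), drop = FALSE]
    }
    total <- total +
      sum(P[seq_len(nrow(Dl)), seq_len(ncol(Dl)), drop = FALSE] *
            exp(-Dl / (2 * params$sigmaC^2)))
  }
  total
}

#' Generic string kernel matrix over a sequence set
#'
#' Pairwise [gsKernel()] values followed by cosine normalization. The
#' full-sequence, kinase-domain and ATP-pocket kernel variants differ only
#' in the sequence set supplied.
#'
#' @param seqs named AAStringSet or named character vector.
#' @inheritParams gsKernel
#' @return A [KernelMatrix-class].
#' @export
gsKernelMatrix <- function(seqs, params = gsParams(),
                           table = blosumDescriptorTable()) {
  seqs <- as.character(.as_aa_set(seqs))
  n <- length(seqs)
  K <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      K[i, j] <- K[j, i] <- gsKernel(seqs[i], seqs[j], params, table)
    }
  }
  kernelMatrix(cosineNormalizeKernel(K), ids = names(seqs), normalized = TRUE)
}

#' Identity protein kernel
#'
#' Fallback when no protein features are available: each protein is similar
#' only to itself, so the model relies on drug-drug similarities and known
#' bioactivities alone. With this kernel, KronRLS decouples into independent
#' drug-side kernel ridge regressions, one per protein column.
#'
#' @param proteinIds character labels.
#' @return A [KernelMatrix-class] holding the exact identity.
#' @export
identityProteinKernel <- function(proteinIds) {
  n <- length(proteinIds)
  kernelMatrix(diag(1, n), ids = proteinIds, normalized = TRUE,
               repair = FALSE)
}

#' Linear kernel from an imported similarity matrix
#'
#' For precomputed pairwise scores (for example 3D-structure alignment
#' energies or sequence identities): optionally self-normalizes
#' \eqn{s(i,j)/\sqrt{s(i,i)s(j,j)}} when the diagonal carries self-scores,
#' then applies the linear kernel with cosine normalization.
#'
#' @param S square numeric matrix of raw pairwise scores.
#' @param selfNormalize divide by the geometric mean of the diagonal
#'   self-scores first (requires a strictly positive diagonal).
#' @return A [KernelMatrix-class].
#' @export
similarityToKernel <- function(S, selfNormalize = TRUE) {
  S <- as.matrix(S)
  if (selfNormalize) {
    d <- diag(S)
    if (any(d <= 0)) stop("self-normalization needs positive self-scores")
    S <- S / sqrt(outer(d, d))
  }
  linearKernel(S)
}

.as_aa_set <- function(seqs) {
  if (is(seqs, "AAStringSet")) return(seqs)
  Biostrings::AAStringSet(seqs)
}

.gs_encode <- function(s, table) {
  chars <- strsplit(as.character(s), "")[[1L]]
  if (!length(chars)) stop("empty sequence")
  unknown <- !(chars %in% rownames(table))
  if (any(unknown)) {
    # unknown residues get the zero descriptor (mismatch-only contribution)
    enc <- matrix(0, length(chars), ncol(table))
    enc[!unknown, ] <- table[chars[!unknown], , drop = FALSE]
    return(enc)
  }
  table[chars, , drop = FALSE]
}
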