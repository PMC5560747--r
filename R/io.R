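#' Read a compound-by-protein bioactivity matrix
#'
#' Parses a rectangular TSV/CSV file with a header row of protein identifiers
#' and a first column of drug identifiers. Empty cells and the missing token
#' (default \code{"NA"}) mark unmeasured affinities; everything else is parsed
#' as a decimal pKi value. Row and column order in the file is preserved.
#'
#' @param path file path.
#' @param missingToken string, in addition to the empty string, interpreted
#'   as a missing cell.
#' @param sep field separator; tab by default, use "," for CSV.
#' @return A [BioactivityMatrix-class].
#' @export
readBioactivityMatrix <- function(path, missingToken = "NA", sep = "\t") {
  tab <- .read_rect(path, sep)
  proteinIds <- tab$header[-1L]
  drugIds <- vapply(tab$rows, `[`, character(1L), 1L)
  .check_unique(drugIds, "drug id")
  .check_unique(proteinIds, "protein id")
  cells <- lapply(tab$rows, `[`, -1L)
  vals <- matrix(NA_real_, length(drugIds), length(proteinIds))
  for (i in seq_along(cells)) {
    x <- cells[[i]]
    miss <- x == "" | x == missingToken
    v <- suppressWarnings(as.numeric(x))
    if (any(!miss & is.na(v)))
      stop(sprintf("non-numeric affinity cell at row %d, column %d",
                   i, which(!miss & is.na(v))[1L]))
    v[miss] <- NA_real_
    vals[i, ] <- v
  }
  bioactivityMatrix(vals, drugIds, proteinIds)
}

#' Write a bioactivity matrix
#'
#' Missing cells are written as \code{"NA"}; values are written at full
#' double precision so that a write-read round trip is exact.
#'
#' @param x a [BioactivityMatrix-class].
#' @param path output file path.
#' @param sep field separator.
#' @export
writeBioactivityMatrix <- function(x, path, sep = "\t") {
  vals <- affinityValues(x)
  vals[!observedMask(x)] <- NA_real_
  .write_labeled_matrix(vals, drugIds(x), proteinIds(x), path, sep)
}

#' Read a binary fingerprint table
#'
#' One row per compound: identifier followed by B bits, each 0 or 1. Any
#' fingerprint length is accepted (881, 1024, 166, 4860-bit variants and so
#' on). Row order is preserved.
#'
#' @inheritParams readBioactivityMatrix
#' @param header logical; if TRUE the first line is skipped as a header.
#' @return list with \code{drugIds} (character) and \code{bits}
#'   (binary integer matrix, one row per compound).
#' @export
readFingerprints <- function(path, sep = "\t", header = FALSE) {
  tab <- .read_rect(path, sep, header = header)
  drugIds <- vapply(tab$rows, `[`, character(1L), 1L)
  .check_unique(drugIds, "drug id")
  bits <- matrix(0L, length(drugIds), length(tab$rows[[1L]]) - 1L)
  for (i in seq_along(tab$rows)) {
    x <- tab$rows[[i]][-1L]
    bad <- !(x %in% c("0", "1"))
    if (any(bad))
      stop(sprintf("non-binary fingerprint cell at row %d, column %d: '%s'",
                   i, which(bad)[1L], x[which(bad)[1L]]))
    bits[i, ] <- as.integer(x)
  }
  rownames(bits) <- drugIds
  list(drugIds = drugIds, bits = bits)
}

#' Write a fingerprint table
#' @param fp list as returned by [readFingerprints()].
#' @param path output path.
#' @param sep field separator.
#' @export
writeFingerprints <- function(fp, path, sep = "\t") {
  lines <- vapply(seq_along(fp$drugIds), function(i)
    paste(c(fp$drugIds[i], fp$bits[i, ]), collapse = sep), character(1L))
  writeLines(lines, path)
}

.aa_standard <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()]; record identifiers are the first
#' whitespace-delimited token of each header and must be unique. The residue
#' policy accepts the 20 standard amino acids plus, optionally, the ambiguity
#' code X; any other character is an error listing the offenders.
#'
#' @param path FASTA file.
#' @param allowX accept the residue X (default TRUE).
#' @return An [Biostrings::AAStringSet] named by identifier.
#' @export
readFastaSequences <- function(path, allowX = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1L), 1L)
  .check_unique(names(seqs), "sequence id")
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence: ", names(seqs)[Biostrings::width(seqs) == 0L][1L])
  allowed <- c(.aa_standard, if (allowX) "X")
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- colnames(freq)[colSums(freq) > 0 & !(colnames(freq) %in% allowed)]
  if (length(extra))
    stop("residues outside the allowed alphabet: ",
         paste(extra, collapse = ", "))
  seqs
}

#' Read a labeled square similarity matrix
#'
#' TSV/CSV with matching row and column labels (for example precomputed
#' 3D-structure alignment scores). Errors if the matrix is not square or the
#' labels disagree.
#'
#' @inheritParams readBioactivityMatrix
#' @return numeric matrix with dimnames.
#' @export
readSimilarityMatrix <- function(path, sep = "\t") {
  tab <- .read_rect(path, sep)
  ids <- vapply(tab$rows, `[`, character(1L), 1L)
  if (!identical(ids, tab$header[-1L]))
    stop("similarity matrix must be square with matching row/column labels")
  m <- do.call(rbind, lapply(tab$rows, function(r) as.numeric(r[-1L])))
  if (anyNA(m)) stop("similarity matrix contains non-numeric cells")
  dimnames(m) <- list(ids, ids)
  m
}

#' Write / read a kernel matrix as labeled TSV
#'
#' @param k a [KernelMatrix-class] (write) or file path (read).
#' @param path output file path.
#' @param sep field separator.
#' @param normalized flag recorded on the object when reading.
#' @return \code{readKernelMatrix} returns a [KernelMatrix-class].
#' @export
writeKernelMatrix <- function(k, path, sep = "\t") {
  .write_labeled_matrix(kernelValues(k), kernelIds(k), kernelIds(k), path, sep)
}

#' @rdname writeKernelMatrix
#' @export
readKernelMatrix <- function(path, sep = "\t", normalized = FALSE) {
  m <- readSimilarityMatrix(path, sep)
  kernelMatrix(m, ids = rownames(m), normalized = normalized, repair = FALSE)
}

#' Write predictions as a three-column table
#'
#' Columns: drug_id, protein_id, predicted_pKi. Written at full precision.
#'
#' @param pred data.frame with columns drug_id, protein_id, predicted_pKi
#'   (extra columns are kept).
#' @param path output path.
#' @param sep field separator.
#' @export
writePredictions <- function(pred, path, sep = "\t") {
  stopifnot(all(c("drug_id", "protein_id", "predicted_pKi") %in% names(pred)))
  num <- vapply(pred, is.numeric, logical(1L))
  pred[num] <- lapply(pred[num], .fmt_full)
  write.table(pred, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a substitution matrix in NCBI flat-file layout
#'
#' Parses the standard whitespace-separated layout ('#' comment lines, a
#' header row of residue symbols, one scored row per residue). The result
#' must be symmetric with strictly positive diagonal for standard residues.
#'
#' @param path flat file path.
#' @return symmetric integer matrix with residue dimnames.
#' @seealso \code{data(BLOSUM50, package = "Biostrings")} for the bundled
#'   default used throughout.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  header <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  ids <- vapply(rows, `[`, character(1L), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(ids, header)
  if (!identical(rownames(m), colnames(m)) || max(abs(m - t(m))) > 0)
    stop("substitution matrix must be symmetric with matching labels")
  std <- intersect(rownames(m), .aa_standard)
  if (any(diag(m[std, std, drop = FALSE]) <= 0))
    stop("substitution matrix diagonal must be positive for standard residues")
  m
}

# full-precision decimal rendering so write->read round-trips exactly
.fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

.write_labeled_matrix <- function(m, rowIds, colIds, path, sep) {
  lines <- c(paste(c("id", colIds), collapse = sep),
             vapply(seq_along(rowIds), function(i)
               paste(c(rowIds[i], .fmt_full(m[i, ])), collapse = sep),
               character(1L)))
  writeLines(lines, path)
}

.read_rect <- function(path, sep, header = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  # trailing separator keeps empty last fields (strsplit drops the final
  # empty token otherwise)
  parts <- strsplit(paste0(lines, sep), sep, fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 which(widths != widths[1L])[1L],
                 widths[which(widths != widths[1L])[1L]], widths[1L]))
  if (header) list(header = parts[[1L]], rows = parts[-1L])
  else list(header = NULL, rows = parts)
}

.check_unique <- function(x, what) {
  if (anyDuplicated(x))
    stop(sprintf("duplicate %s: '%s'", what, x[duplicated(x)][1L]))
  invisible(x)
}

#' The bundled BLOSUM50 substitution matrix
#'
#' Convenience accessor for the BLOSUM50 matrix shipped with Biostrings,
#' used as the default for all Smith-Waterman alignments and as the
#' amino-acid descriptor table of the generic string kernel.
#'
#' @return integer substitution matrix.
#' @export
blosum50 <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}
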