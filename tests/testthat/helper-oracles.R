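# Independent reference implementations used only to validate the package's
# fast paths. Deliberately naive: direct loops and textbook recursions.

# Smith-Waterman local alignment with affine gaps (Gotoh), quadratic space.
# A gap of length L costs open + L * ext, matching the package convention.
sw_oracle <- function(s1, s2, sub, open = 10, ext = 0.5) {
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)   # gap in s2 (vertical)
  Iy <- matrix(-Inf, n + 1L, m + 1L)   # gap in s1 (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- sub[a[i], b[j]]
      M[i + 1L, j + 1L] <- max(0,
        M[i, j] + sc, Ix[i, j] + sc, Iy[i, j] + sc)
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                Iy[i + 1L, j] - ext)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# generic string kernel by literal triple summation over substring lengths
# and 0-based start offsets
gs_oracle <- function(s, sp, L, sigmaP, sigmaC, table) {
  enc <- function(x) {
    ch <- strsplit(x, "")[[1L]]
    t(vapply(ch, function(c_) {
      if (c_ %in% rownames(table)) table[c_, ] else numeric(ncol(table))
    }, numeric(ncol(table))))
  }
  A <- enc(s); B <- enc(sp)
  total <- 0
  for (l in seq_len(L)) {
    if (l > nrow(A) || l > nrow(B)) next
    for (i in 0:(nrow(A) - l)) {
      for (j in 0:(nrow(B) - l)) {
        psiA <- as.vector(t(A[(i + 1):(i + l), , drop = FALSE]))
        psiB <- as.vector(t(B[(j + 1):(j + l), , drop = FALSE]))
        total <- total +
          exp(-(i - j)^2 / (2 * sigmaP^2)) *
          exp(-sum((psiA - psiB)^2) / (2 * sigmaC^2))
      }
    }
  }
  total
}

# ROC-AUC by exhaustive concordant/discordant/tied pair counting
auc_oracle <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# weighted-row-average imputation by direct per-cell loops
impute_oracle <- function(vals, obs, S) {
  out <- vals
  for (i in seq_len(nrow(vals))) for (j in seq_len(ncol(vals))) {
    if (obs[i, j]) next
    k <- which(obs[i, ])
    if (length(k)) {
      w <- S[j, k]
      out[i, j] <- if (sum(w) > 0) sum(w * vals[i, k]) / sum(w)
                   else mean(vals[i, k])
    } else {
      kc <- which(obs[, j])
      out[i, j] <- if (length(kc)) mean(vals[kc, j]) else mean(vals[obs])
    }
  }
  out
}

# random PSD kernel with unit-ish scale
random_kernel <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  K <- crossprod(A) / n
  0.5 * (K + t(K))
}

make_fixture <- function(nD = 12L, nP = 8L, seed = 3L, ...) {
  simulateBindingData(syntheticConfig(nDrugs = nD, nProteins = nP,
                                      seed = seed, ...))
}
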