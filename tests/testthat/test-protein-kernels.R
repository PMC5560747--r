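random_seqs <- function(n, len, seed) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                   "M","F","P","S","T","W","Y","V"),
                 sample(len, 1L), replace = TRUE), collapse = ""),
    character(1L)), paste0("p", seq_len(n)))
}

test_that("Smith-Waterman scores match an independent affine-gap DP oracle", {
  sub <- blosum50()
  # ungapped diagonal optimum: three A-A matches at 5 each
  expect_equal(smithWatermanScore("AAA", "AAA"), 15)
  seqs <- random_seqs(8, c(5, 20), seed = 10)
  for (i in 1:7) {
    s1 <- seqs[[i]]; s2 <- seqs[[i + 1]]
    expect_equal(smithWatermanScore(s1, s2), sw_oracle(s1, s2, sub))
    expect_equal(smithWatermanScore(s1, s2), smithWatermanScore(s2, s1))
  }
})

test_that("normalized SW similarity is 1 on the diagonal and bounded by 1", {
  seqs <- random_seqs(6, c(8, 25), seed = 11)
  S <- normalizedSWMatrix(seqs)
  expect_equal(diag(S), setNames(rep(1, 6), names(seqs)))
  expect_equal(S, t(S))
  expect_true(all(S <= 1 + 1e-12))
  expect_equal(normalizedSWSimilarity(seqs[[1]], seqs[[1]]), 1)
  # matrix entries equal pairwise calls
  expect_equal(S[2, 5], normalizedSWSimilarity(seqs[[2]], seqs[[5]]))
})

test_that("SW+ profiles are entrywise normalized SW scores against the reference", {
  targets <- random_seqs(3, c(10, 18), seed = 12)
  reference <- random_seqs(5, c(10, 18), seed = 13)
  P <- swPlusProfiles(targets, reference)
  expect_equal(dim(P), c(3L, 5L))
  for (i in 1:3) for (l in 1:5)
    expect_equal(P[i, l],
                 normalizedSWSimilarity(targets[[i]], reference[[l]]))
  # reference = targets themselves puts 1.0 at each row's own column
  Pself <- swPlusProfiles(targets, targets)
  expect_equal(diag(Pself), setNames(rep(1, 3), names(targets)))
  # downstream kernel passes the standard checks
  K <- linearKernel(P, ids = names(targets))
  expect_true(isNormalized(K))
})

test_that("generic string kernel matches the naive triple-loop oracle", {
  tab <- blosumDescriptorTable()
  expect_equal(gsKernel("A", "A", gsParams(L = 1)), 1)

  # four-term hand expansion for s = s' = "AC", L = 1
  p <- gsParams(L = 1, sigmaP = 1.3, sigmaC = 9)
  dAC <- sum((tab["A", ] - tab["C", ])^2)
  expect_equal(gsKernel("AC", "AC", p),
               2 + 2 * exp(-1 / (2 * p$sigmaP^2)) * exp(-dAC / (2 * p$sigmaC^2)))

  set.seed(14)
  for (rep in 1:10) {
    s <- paste(sample(rownames(tab), sample(2:8, 1), replace = TRUE), collapse = "")
    sp <- paste(sample(rownames(tab), sample(2:8, 1), replace = TRUE), collapse = "")
    L <- sample(1:3, 1)
    prm <- gsParams(L = L, sigmaP = runif(1, 0.5, 3), sigmaC = runif(1, 3, 20))
    expect_equal(gsKernel(s, sp, prm),
                 gs_oracle(s, sp, L, prm$sigmaP, prm$sigmaC, tab))
    expect_equal(gsKernel(s, sp, prm), gsKernel(sp, s, prm))
  }
})

test_that("generic string kernel is monotone in L and tolerates L beyond |s|", {
  set.seed(15)
  s <- "ACDEFGH"; sp <- "MKLAC"
  vals <- vapply(1:6, function(L) gsKernel(s, sp, gsParams(L = L)), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  # lengths beyond the shorter sequence add nothing
  expect_equal(gsKernel(s, sp, gsParams(L = 10)),
               gsKernel(s, sp, gsParams(L = 5)))
})

test_that("protein kernel matrices pass PSD and unit-diagonal checks", {
  seqs <- random_seqs(5, c(10, 20), seed = 16)
  for (K in list(swKernel(seqs), gsKernelMatrix(seqs))) {
    V <- kernelValues(K)
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_lt(max(abs(diag(V) - 1)), 1e-10)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("identity protein kernel reduces KronRLS to per-protein drug ridge", {
  ids <- paste0("p", 1:3)
  K <- identityProteinKernel(ids)
  expect_equal(kernelValues(K), diag(1, 3), ignore_attr = TRUE)

  set.seed(17)
  KD <- random_kernel(6, 18)
  Y <- matrix(rnorm(6 * 3, 7), 6)
  lam <- 0.4
  model <- kronrlsFit(KD, kernelValues(K), Y, lam)
  percol <- sapply(1:3, function(j)
    KD %*% solve(KD + lam * diag(6), Y[, j]))
  expect_equal(fitted(model), percol, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("imported 3D-style similarity matrices become valid kernels", {
  set.seed(18)
  raw <- crossprod(matrix(rnorm(16), 4)) + diag(4)   # positive self-scores
  K <- similarityToKernel(raw)
  expect_true(isNormalized(K))
  expect_error(similarityToKernel(raw - diag(diag(raw))), "positive self-scores")
})
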