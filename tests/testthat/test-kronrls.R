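test_that("weighted-row-average imputation matches the per-cell oracle", {
  # hand case: row (5, missing, 7) with weights 0.5 to both observed proteins
  vals <- rbind(c(5, NA, 7))
  S <- diag(1, 3); S[2, 1] <- S[1, 2] <- 0.5; S[2, 3] <- S[3, 2] <- 0.5
  Y <- bioactivityMatrix(vals, "d1", paste0("p", 1:3))
  expect_equal(affinityValues(imputeMissing(Y, S))[1, 2], 6)

  # degenerate weight (1, 0) picks the first observed value
  S2 <- diag(1, 3); S2[2, 1] <- S2[1, 2] <- 1
  expect_equal(affinityValues(imputeMissing(Y, S2))[1, 2], 5)

  # fully observed input is returned unchanged
  Yfull <- bioactivityMatrix(matrix(1:6 + 0.5, 2, 3),
                             c("a", "b"), paste0("p", 1:3))
  expect_identical(imputeMissing(Yfull, diag(1, 3)), Yfull)

  set.seed(20)
  vals <- matrix(rnorm(8 * 6, 7), 8)
  obs <- matrix(runif(48) > 0.3, 8)
  obs[3, ] <- FALSE                       # one fully missing row
  v2 <- vals; v2[!obs] <- NA
  S <- cosineNormalizeKernel(tcrossprod(matrix(runif(18), 6)) + diag(6))
  Yr <- bioactivityMatrix(v2, paste0("d", 1:8), paste0("p", 1:6),
                          observed = obs)
  got <- affinityValues(imputeMissing(Yr, S))
  expect_equal(got, impute_oracle(v2, obs, S), ignore_attr = TRUE)
  expect_equal(unname(observedMask(imputeMissing(Yr, S))), obs)  # mask preserved
  expect_identical(got[obs], vals[obs])                      # observed untouched
})

test_that("explicit Kronecker solve handles the scalar and shrinkage limits", {
  # (1 + lambda) alpha = y with all-ones kernels
  ex <- kronrlsSolveExplicit(matrix(1), matrix(1), matrix(2), 1)
  expect_equal(ex$alpha, 1)
  expect_equal(ex$fitted[1, 1], 1)

  set.seed(22)
  KD <- random_kernel(3, 23); KP <- random_kernel(4, 24)
  Y <- matrix(rnorm(12), 3)
  big <- kronrlsSolveExplicit(KD, KP, Y, 1e8)
  expect_lt(max(abs(big$fitted)), 1e-4)   # predictions shrink toward zero
  expect_lt(sqrt(sum(big$alpha^2)), sqrt(sum(Y^2)) / 1e8 * 1.01)

  # alpha agrees with a generic dense solve
  lam <- 0.8
  K <- kronecker(KD, KP)
  ref <- solve(K + lam * diag(12), as.vector(t(Y)))
  expect_equal(kronrlsSolveExplicit(KD, KP, Y, lam)$alpha, ref)

  expect_error(kronrlsSolveExplicit(diag(70), diag(70), matrix(0, 70, 70), 1),
               "4096")
})

test_that("eigendecomposition fit equals the explicit solve across random instances", {
  for (s in 1:20) {
    set.seed(s)
    nD <- sample(2:5, 1); nP <- sample(2:6, 1)
    KD <- random_kernel(nD, s); KP <- random_kernel(nP, s + 100)
    Y <- matrix(rnorm(nD * nP, 7), nD)
    lam <- 2^runif(1, -8, 4)
    ex <- kronrlsSolveExplicit(KD, KP, Y, lam)
    m <- kronrlsFit(KD, KP, Y, lam)
    expect_lt(max(abs(ex$alpha - dualVector(m))), 1e-8)
    expect_lt(max(abs(ex$fitted - fitted(m))), 1e-8)
    # predict() at a training pair reproduces the fitted value
    i <- sample(nD, 1); j <- sample(nP, 1)
    expect_equal(predict(m, KD[i, ], KP[j, ]), fitted(m)[i, j])
    # and matches (kD (x) kP) alpha for a random query
    kD <- rnorm(nD); kP <- rnorm(nP)
    expect_equal(predict(m, kD, kP),
                 sum(kronecker(kD, kP) * ex$alpha), tolerance = 1e-8)
  }
})

test_that("identity kernels with lambda 1 halve the labels", {
  Y <- matrix(rnorm(12, 7), 3)
  m <- kronrlsFit(diag(3), diag(4), Y, 1)
  expect_equal(fitted(m), Y / 2, ignore_attr = TRUE)
})

test_that("fit is invariant to eigenbasis sign and order perturbations", {
  set.seed(30)
  KD <- random_kernel(5, 31); KP <- random_kernel(4, 32)
  Y <- matrix(rnorm(20, 7), 5)
  m <- kronrlsFit(KD, KP, Y, 0.3)
  # rebuild the kernels from a permuted, sign-flipped eigenbasis; predictions
  # must not change
  e <- eigen(KD, symmetric = TRUE)
  perm <- sample(5); signs <- sample(c(-1, 1), 5, replace = TRUE)
  KD2 <- (e$vectors[, perm] %*% diag(signs)) %*% diag(e$values[perm]) %*%
    t(e$vectors[, perm] %*% diag(signs))
  m2 <- kronrlsFit(KD2, KP, Y, 0.3)
  expect_equal(fitted(m2), fitted(m), tolerance = 1e-10)
})

test_that("predictions are linear in the label matrix", {
  set.seed(33)
  KD <- random_kernel(4, 34); KP <- random_kernel(3, 35)
  Y1 <- matrix(rnorm(12), 4); Y2 <- matrix(rnorm(12), 4)
  a <- 1.7; b <- -0.4
  f <- function(Y) fitted(kronrlsFit(KD, KP, Y, 0.5))
  expect_equal(f(a * Y1 + b * Y2), a * f(Y1) + b * f(Y2), tolerance = 1e-9)
})

test_that("fitted values interpolate the labels as lambda tends to zero", {
  set.seed(36)
  KD <- random_kernel(4, 37) + diag(4)   # strictly PD
  KP <- random_kernel(3, 38) + diag(3)
  Y <- matrix(rnorm(12, 7), 4)
  expect_equal(fitted(kronrlsFit(KD, KP, Y, 1e-10)), Y,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are rejected", {
  Y <- bioactivityMatrix(matrix(c(1, NA, 3, 4), 2, 2))
  expect_error(kronrlsFit(diag(2), diag(2), Y, 1), "imputeMissing")
  expect_error(kronrlsFit(diag(2), diag(2), matrix(0, 2, 2), 0), "positive")
  m <- kronrlsFit(diag(2), diag(2), matrix(rnorm(4), 2), 1)
  expect_error(predict(m, c(1, 2, 3), c(1, 0)), "columns")
  expect_equal(predict(m, c(0, 0), c(1, 0)), 0)  # zero query vector
})

test_that("hat diagonal gives exact single-label substitution updates", {
  set.seed(40)
  KD <- random_kernel(4, 41); KP <- random_kernel(3, 42)
  Y <- matrix(rnorm(12, 7), 4)
  lam <- 0.7
  m <- kronrlsFit(KD, KP, Y, lam)
  H <- hatDiagonal(m)
  Y2 <- Y; delta <- 1.3; Y2[2, 3] <- Y[2, 3] + delta
  m2 <- kronrlsFit(KD, KP, Y2, lam)
  expect_equal(fitted(m2)[2, 3], fitted(m)[2, 3] + H[2, 3] * delta,
               tolerance = 1e-10)
  expect_true(all(H >= -1e-12 & H <= 1 + 1e-12))
})
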