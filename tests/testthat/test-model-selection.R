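toy_setup <- function(nD = 3L, nP = 3L, seed = 50L, missing = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(nD * nP, 7), nD,
                 dimnames = list(paste0("d", 1:nD), paste0("p", 1:nP)))
  if (missing > 0) vals[sample(length(vals), missing)] <- NA
  Y <- bioactivityMatrix(vals)
  KD <- kernelMatrix(random_kernel(nD, seed + 1) + diag(nD),
                     ids = drugIds(Y))
  KP <- kernelMatrix(random_kernel(nP, seed + 2) + diag(nP),
                     ids = proteinIds(Y))
  SP <- cosineNormalizeKernel(kernelValues(KP))
  list(Y = Y, KD = KD, KP = KP, SP = SP)
}

test_that("nested LOO-CV matches a brute-force refit oracle on a toy matrix", {
  tt <- toy_setup(3, 3, seed = 50)
  res <- nestedLOOCV(tt$Y, fixedKernel(tt$KD), fixedKernel(tt$KP),
                     lambda = 1, proteinSimilarity = tt$SP)
  pr <- cvPredictions(res)
  vals <- affinityValues(tt$Y)
  for (k in seq_len(nrow(pr))) {
    i <- match(pr$drug_id[k], drugIds(tt$Y))
    j <- match(pr$protein_id[k], proteinIds(tt$Y))
    v2 <- vals; v2[i, j] <- NA
    Yimp <- imputeMissing(bioactivityMatrix(v2, drugIds(tt$Y),
                                            proteinIds(tt$Y)), tt$SP)
    ex <- kronrlsSolveExplicit(kernelValues(tt$KD), kernelValues(tt$KP),
                               affinityValues(Yimp), 1)
    expect_equal(pr$predicted[k], ex$fitted[i, j], tolerance = 1e-8)
  }
  # a single grid point is always the selected one
  expect_true(all(cvSelected(res)$lambda == 1))
})

test_that("nested LDO-CV matches a brute-force refit oracle with one grid point", {
  tt <- toy_setup(8, 4, seed = 60, missing = 5)
  res <- nestedLDOCV(tt$Y, fixedKernel(tt$KD), fixedKernel(tt$KP),
                     lambda = 0.5, proteinSimilarity = tt$SP, seed = 9)
  pr <- cvPredictions(res)
  vals <- affinityValues(tt$Y); obs <- observedMask(tt$Y)
  KDv <- kernelValues(tt$KD); KPv <- kernelValues(tt$KP)
  for (i in 1:8) {
    tr <- setdiff(1:8, i)
    Ysub <- bioactivityMatrix(vals[tr, , drop = FALSE],
                              drugIds(tt$Y)[tr], proteinIds(tt$Y),
                              observed = obs[tr, , drop = FALSE])
    Yimp <- affinityValues(imputeMissing(Ysub, tt$SP))
    ex <- kronrlsSolveExplicit(KDv[tr, tr], KPv, Yimp, 0.5)
    A <- matrix(ex$alpha, ncol(vals), length(tr))   # proteins x training drugs
    predRow <- as.vector(KPv %*% A %*% KDv[i, tr])
    for (j in which(obs[i, ])) {
      row <- pr[pr$drug_id == drugIds(tt$Y)[i] &
                  pr$protein_id == proteinIds(tt$Y)[j], ]
      expect_equal(row$predicted, predRow[j], tolerance = 1e-8)
    }
  }
})

test_that("interaction-profile kernels are refused in the scenario they would leak", {
  tt <- toy_setup(8, 8, seed = 70)
  expect_error(nestedLDOCV(tt$Y, gipBuilder(), fixedKernel(tt$KP),
                           lambda = 1, proteinSimilarity = tt$SP),
               "scenario violation")
  expect_error(nestedLTOCV(tt$Y, fixedKernel(tt$KD), gipBuilder(),
                           lambda = 1, proteinSimilarity = tt$SP),
               "scenario violation")
})

test_that("held-out entry labels never reach the LOO fold model (sentinel test)", {
  d <- make_fixture(8, 6, seed = 80)
  Y <- d$bioactivity
  SP <- normalizedSWMatrix(d$sequences)
  KP <- linearKernel(SP)
  cells <- which(observedMask(Y), arr.ind = TRUE)
  target <- cells[5, ]

  run <- function(Ymod) {
    res <- nestedLOOCV(Ymod, gipBuilder(), fixedKernel(KP),
                       lambda = c(0.1, 1), proteinSimilarity = SP)
    pr <- cvPredictions(res)
    pr$predicted[pr$drug_id == drugIds(Y)[target[1]] &
                   pr$protein_id == proteinIds(Y)[target[2]]]
  }
  vals2 <- affinityValues(Y)
  vals2[target[1], target[2]] <- vals2[target[1], target[2]] + 5  # sentinel
  Y2 <- bioactivityMatrix(vals2, drugIds(Y), proteinIds(Y),
                          observed = observedMask(Y))
  # perturbing only the held-out label leaves that fold's prediction intact:
  # imputation, the interaction-profile drug kernel and the fitted model all
  # excluded it
  expect_identical(run(Y), run(Y2))
})

test_that("held-out compounds never reach the LDO fold model (sentinel test)", {
  d <- make_fixture(9, 6, seed = 81)
  Y <- d$bioactivity
  SP <- normalizedSWMatrix(d$sequences)
  KD <- linearKernel(tanimotoMatrix(d$fingerprints$bits))
  run <- function(Ymod) {
    res <- nestedLDOCV(Ymod, fixedKernel(KD), gipBuilder(),
                       lambda = c(0.1, 1), proteinSimilarity = SP, seed = 4)
    pr <- cvPredictions(res)
    pr$predicted[pr$drug_id == drugIds(Y)[3]]
  }
  vals2 <- affinityValues(Y)
  vals2[3, observedMask(Y)[3, ]] <- vals2[3, observedMask(Y)[3, ]] + 5
  Y2 <- bioactivityMatrix(vals2, drugIds(Y), proteinIds(Y),
                          observed = observedMask(Y))
  expect_identical(run(Y), run(Y2))
})

test_that("cross-validation is reproducible under a fixed seed", {
  d <- make_fixture(8, 5, seed = 82)
  SP <- normalizedSWMatrix(d$sequences)
  KD <- linearKernel(tanimotoMatrix(d$fingerprints$bits))
  KP <- linearKernel(SP)
  r1 <- nestedLDOCV(d$bioactivity, fixedKernel(KD), fixedKernel(KP),
                    lambda = c(0.1, 1), proteinSimilarity = SP, seed = 7)
  r2 <- nestedLDOCV(d$bioactivity, fixedKernel(KD), fixedKernel(KP),
                    lambda = c(0.1, 1), proteinSimilarity = SP, seed = 7)
  expect_identical(cvPredictions(r1), cvPredictions(r2))
  expect_identical(cvSelected(r1), cvSelected(r2))
})

test_that("grid search rejects an empty grid and breaks ties toward larger lambda", {
  tt <- toy_setup(3, 3, seed = 90)
  expect_error(nestedLOOCV(tt$Y, fixedKernel(tt$KD), fixedKernel(tt$KP),
                           lambda = numeric(0), proteinSimilarity = tt$SP),
               "empty lambda grid")
  # duplicated grid values force exact ties; the reported choice must be the
  # (identical) larger value
  res <- nestedLOOCV(tt$Y, fixedKernel(tt$KD), fixedKernel(tt$KP),
                     lambda = c(1, 1), proteinSimilarity = tt$SP)
  expect_true(all(cvSelected(res)$lambda == 1))
})

test_that("selectAndRefit returns a model trained with a grid point", {
  d <- make_fixture(10, 6, seed = 91)
  SP <- normalizedSWMatrix(d$sequences)
  KP <- linearKernel(SP)
  grid <- 2^seq(-5, 3, 2)
  m <- selectAndRefit(d$bioactivity, gipBuilder(), fixedKernel(KP),
                      "bioactivity_imputation", lambda = grid,
                      proteinSimilarity = SP)
  sel <- attr(m, "selected")
  expect_true(sel$lambda %in% grid)
  expect_s4_class(m, "KronRLSModel")
  # new-drug selection path with a fixed drug kernel
  KD <- linearKernel(tanimotoMatrix(d$fingerprints$bits))
  m2 <- selectAndRefit(d$bioactivity, fixedKernel(KD), fixedKernel(KP),
                       "new_drug", lambda = grid, proteinSimilarity = SP,
                       seed = 2)
  expect_true(attr(m2, "selected")$lambda %in% grid)
})

test_that("new-pair fold plans partition both axes into disjoint groups", {
  folds <- newPairFolds(paste0("d", 1:11), paste0("p", 1:7), nFolds = 3, seed = 5)
  expect_length(folds, 3L)
  expect_identical(attr(folds, "scenario"), "new_pair")
  allD <- unlist(lapply(folds, `[[`, "drugs"))
  allP <- unlist(lapply(folds, `[[`, "proteins"))
  expect_setequal(allD, paste0("d", 1:11))
  expect_setequal(allP, paste0("p", 1:7))
  expect_false(anyDuplicated(allD) > 0)
  expect_false(anyDuplicated(allP) > 0)
})
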