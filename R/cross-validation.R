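#' Default regularization grid
#'
#' Thirteen log-spaced candidates \code{2^seq(-15, 9, by = 2)}, configurable
#' everywhere a grid is accepted.
#'
#' @return numeric vector of positive lambda values.
#' @export
lambdaGrid <- function() 2^seq(-15, 9, by = 2)

#' Kernel builders for cross-validation
#'
#' Cross-validation needs to rebuild interaction-profile kernels inside each
#' fold (with the held-out unit's affinities removed) while precomputed
#' feature kernels stay fixed. \code{fixedKernel} wraps a ready
#' [KernelMatrix-class]; \code{gipBuilder} requests a Gaussian
#' interaction-profile kernel rebuilt per fold, with the width either fixed
#' (numeric \code{sigma}) or chosen per fold from the 0.1/0.5/0.9
#' pairwise-distance quantile rule (\code{sigma = NULL}), the quantile level
#' then acting as the grid dimension.
#'
#' @param kernel a [KernelMatrix-class].
#' @param sigma numeric vector of candidate widths, or NULL for the quantile
#'   rule.
#' @return an object of class \code{"kernelBuilder"}.
#' @export
fixedKernel <- function(kernel) {
  stopifnot(is(kernel, "KernelMatrix"))
  structure(list(type = "fixed", kernel = kernel), class = "kernelBuilder")
}

#' @rdname fixedKernel
#' @export
gipBuilder <- function(sigma = NULL) {
  if (!is.null(sigma) && any(sigma <= 0)) stop("'sigma' must be positive")
  structure(list(type = "gip", sigma = sigma), class = "kernelBuilder")
}

.is_gip <- function(builder) identical(builder$type, "gip")

# GIP kernel candidates for one fold. profiles: rows = axis objects (fully
# imputed), with the held-out partner column(s) already excluded.
.gip_candidates <- function(builder, profiles) {
  if (is.null(builder$sigma)) {
    sig <- sigmaGridFromDistances(profiles)
    lab <- c("q10", "q50", "q90")
    keep <- sig > 0
    sig <- sig[keep]
    lab <- lab[keep]
    sig_u <- !duplicated(sig)
    sig <- sig[sig_u]
    lab <- lab[sig_u]
  } else {
    sig <- builder$sigma
    lab <- paste0("sigma=", signif(sig, 4))
  }
  lapply(seq_along(sig), function(k)
    list(kernel = kernelValues(gipKernel(profiles, sig[k])),
         label = lab[k], sigma = sig[k]))
}

.fixed_candidate <- function(builder, keepIds = NULL) {
  K <- kernelValues(builder$kernel)
  if (!is.null(keepIds)) {
    idx <- match(keepIds, kernelIds(builder$kernel))
    if (anyNA(idx)) stop("kernel is missing ids required by the fold")
    K <- K[idx, idx, drop = FALSE]
  }
  list(list(kernel = K, label = "fixed", sigma = NA_real_))
}

.eigs <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, s = pmax(e$values, 0))
}

# fitted values and hat diagonal for cached eigendecompositions
.fold_fit <- function(eD, eP, Ym, lambda) {
  M <- crossprod(eP$U, t(Ym)) %*% eD$U
  denom <- outer(eP$s, eD$s) + lambda
  C <- M / denom
  G <- C * outer(eP$s, eD$s)
  F <- t(eP$U %*% G %*% t(eD$U))
  W <- outer(eD$s, eP$s) / (outer(eD$s, eP$s) + lambda)
  H <- (eD$U^2) %*% W %*% t(eP$U^2)
  list(F = F, H = H, C = C)
}

# leave-one-entry-out imputed replacement values: for every observed cell,
# the value the weighted row average would impute if that cell were missing
.loo_imputed_values <- function(vals, obs, S) {
  out <- matrix(NA_real_, nrow(vals), ncol(vals))
  globalMean <- mean(vals[obs])
  for (r in seq_len(nrow(vals))) {
    oq <- which(obs[r, ])
    if (!length(oq)) next
    y <- vals[r, oq]
    W <- S[oq, oq, drop = FALSE]
    num <- as.vector(W %*% y) - diag(W) * y
    den <- rowSums(W) - diag(W)
    v <- num / den
    bad <- !is.finite(v) | den <= 0
    if (any(bad)) {
      # no usable weights: unweighted mean of the other observed cells
      othersum <- sum(y)
      v[bad] <- if (length(y) > 1L) (othersum - y[bad]) / (length(y) - 1L)
                else globalMean
    }
    out[r, oq] <- v
  }
  out
}

.tie_break_best <- function(rmses, lambdas) {
  best <- which(rmses == min(rmses))
  best[which.max(lambdas[best])]
}

.restore_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  else NULL
}

.with_seed <- function(seed, expr) {
  old <- .restore_rng()
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Nested leave-one-out cross-validation (Bioactivity Imputation scenario)
#'
#' Outer loop: each observed compound-protein entry is held out in turn (its
#' cell masked before any imputation or interaction-profile kernel is
#' computed, so the held-out label never reaches the trained fold model).
#' For interaction-profile kernels, the held-out pair's partner column (row)
#' is additionally excluded from the profiles. Inner loop: exact closed-form
#' leave-one-entry-out over the remaining observed entries scores every grid
#' point by RMSE; the winner (ties broken toward larger lambda) is refit on
#' all remaining entries and the held-out entry's prediction recorded.
#'
#' Imputed cells never enter performance aggregation: only originally
#' observed cells are folds, and inner RMSE is computed against measured
#' values only.
#'
#' @param Y a [BioactivityMatrix-class] with at least 2 observed entries.
#' @param drugKernel,proteinKernel kernel builders ([fixedKernel()] or
#'   [gipBuilder()]).
#' @param lambda numeric grid of regularization candidates.
#' @param proteinSimilarity square similarity matrix over the protein axis
#'   used for imputation weights; identity (plain row means) by default.
#' @param seed integer, recorded for provenance (the plan is deterministic).
#' @return A [CVResult-class].
#' @export
nestedLOOCV <- function(Y, drugKernel, proteinKernel, lambda = lambdaGrid(),
                        proteinSimilarity = NULL, seed = 1L) {
  if (!length(lambda)) stop("empty lambda grid")
  vals <- affinityValues(Y)
  obs <- observedMask(Y)
  if (sum(obs) < 2L) stop("need at least 2 observed entries")
  nP <- ncol(vals)
  if (is.null(proteinSimilarity)) proteinSimilarity <- diag(1, nP)
  S <- as.matrix(proteinSimilarity)
  cells <- which(obs, arr.ind = TRUE)
  preds <- numeric(nrow(cells))
  sel <- vector("list", nrow(cells))

  fixedD <- if (!.is_gip(drugKernel))
    .fixed_candidate(drugKernel, drugIds(Y)) else NULL
  fixedP <- if (!.is_gip(proteinKernel))
    .fixed_candidate(proteinKernel, proteinIds(Y)) else NULL
  eFixedD <- if (!is.null(fixedD)) .eigs(fixedD[[1L]]$kernel)
  eFixedP <- if (!is.null(fixedP)) .eigs(fixedP[[1L]]$kernel)

  for (f in seq_len(nrow(cells))) {
    i <- cells[f, 1L]; j <- cells[f, 2L]
    obsF <- obs
    obsF[i, j] <- FALSE
    valsF <- vals
    valsF[i, j] <- NA_real_
    Yf <- bioactivityMatrix(valsF, drugIds(Y), proteinIds(Y), observed = obsF)
    Yimp <- imputeMissing(Yf, S)
    Vimp <- affinityValues(Yimp)

    candD <- if (.is_gip(drugKernel))
      .gip_candidates(drugKernel, Vimp[, -j, drop = FALSE]) else fixedD
    candP <- if (.is_gip(proteinKernel))
      .gip_candidates(proteinKernel, t(Vimp)[, -i, drop = FALSE]) else fixedP

    ystar <- .loo_imputed_values(valsF, obsF, S)
    innerIdx <- which(obsF)          # linear indices of inner entries
    yTrue <- vals[innerIdx]
    yRepl <- ystar[innerIdx]

    combos <- list(); rms <- numeric(); lam <- numeric()
    comboFit <- list()
    for (a in seq_along(candD)) {
      eD <- if (.is_gip(drugKernel)) .eigs(candD[[a]]$kernel) else eFixedD
      for (b in seq_along(candP)) {
        eP <- if (.is_gip(proteinKernel)) .eigs(candP[[b]]$kernel) else eFixedP
        for (l in lambda) {
          ff <- .fold_fit(eD, eP, Vimp, l)
          pin <- ff$F[innerIdx] + ff$H[innerIdx] * (yRepl - Vimp[innerIdx])
          combos[[length(combos) + 1L]] <-
            list(lambda = l, sigmaD = candD[[a]]$sigma,
                 sigmaP = candP[[b]]$sigma, labelD = candD[[a]]$label,
                 labelP = candP[[b]]$label)
          rms <- c(rms, sqrt(mean((pin - yTrue)^2)))
          lam <- c(lam, l)
          comboFit[[length(comboFit) + 1L]] <- ff$F[i, j]
        }
      }
    }
    k <- .tie_break_best(rms, lam)
    preds[f] <- comboFit[[k]]
    sel[[f]] <- data.frame(fold = f, drug_id = drugIds(Y)[i],
                           protein_id = proteinIds(Y)[j],
                           lambda = combos[[k]]$lambda,
                           sigmaD = combos[[k]]$sigmaD,
                           sigmaP = combos[[k]]$sigmaP,
                           inner_rmse = rms[k],
                           stringsAsFactors = FALSE)
  }

  predDf <- data.frame(
    drug_id = drugIds(Y)[cells[, 1L]],
    protein_id = proteinIds(Y)[cells[, 2L]],
    measured = vals[obs], predicted = preds,
    fold = seq_len(nrow(cells)), stringsAsFactors = FALSE)
  new("CVResult", scenario = "bioactivity_imputation",
      predictions = predDf, selected = do.call(rbind, sel),
      pearson = cor(predDf$measured, predDf$predicted),
      rmse = sqrt(mean((predDf$measured - predDf$predicted)^2)),
      seed = as.integer(seed))
}

#' Nested leave-drug-out / leave-target-out cross-validation
#'
#' \code{nestedLDOCV} evaluates the New Drug scenario: each compound row is
#' held out in turn, and its row and column are removed from the drug kernel
#' before training. Interaction-profile kernels on the drug side are a
#' scenario violation (a new compound has no bioactivity profile) and raise
#' an error; protein-side interaction profiles are rebuilt per fold from
#' training rows only. Inner model selection removes disjoint random folds
#' of \code{innerSize} compounds at a time (seeded, \code{ceiling(n/5)}
#' folds by default) and scores each grid point by RMSE over the inner test
#' rows; ties break toward larger lambda. \code{nestedLTOCV} is the
#' symmetric New Target design on the protein axis (protein-side interaction
#' profiles disallowed there instead).
#'
#' @inheritParams nestedLOOCV
#' @param innerSize number of units removed per inner fold (default 5).
#' @param seed integer controlling the random inner folds.
#' @return A [CVResult-class].
#' @export
nestedLDOCV <- function(Y, drugKernel, proteinKernel, lambda = lambdaGrid(),
                        proteinSimilarity = NULL, innerSize = 5L, seed = 1L) {
  if (.is_gip(drugKernel))
    stop("scenario violation: interaction-profile drug kernels are ",
         "unavailable for a new compound (New Drug scenario)")
  .nested_unit_cv(Y, drugKernel, proteinKernel, lambda, proteinSimilarity,
                  innerSize, seed, axis = 1L, scenario = "new_drug")
}

#' @rdname nestedLDOCV
#' @export
nestedLTOCV <- function(Y, drugKernel, proteinKernel, lambda = lambdaGrid(),
                        proteinSimilarity = NULL, innerSize = 5L, seed = 1L) {
  if (.is_gip(proteinKernel))
    stop("scenario violation: interaction-profile protein kernels are ",
         "unavailable for a new target (New Target scenario)")
  .nested_unit_cv(Y, drugKernel, proteinKernel, lambda, proteinSimilarity,
                  innerSize, seed, axis = 2L, scenario = "new_target")
}

# shared machinery for leave-drug-out (axis = 1) and leave-target-out
# (axis = 2). "unit" is a row (drug) or column (protein).
.nested_unit_cv <- function(Y, drugKernel, proteinKernel, lambda,
                            proteinSimilarity, innerSize, seed, axis,
                            scenario) {
  if (!length(lambda)) stop("empty lambda grid")
  vals <- affinityValues(Y)
  obs <- observedMask(Y)
  nUnit <- dim(vals)[axis]
  if (nUnit < innerSize + 2L)
    stop("need at least innerSize + 2 units on the held-out axis")
  nP <- ncol(vals)
  if (is.null(proteinSimilarity)) proteinSimilarity <- diag(1, nP)
  S <- as.matrix(proteinSimilarity)
  unitIds <- if (axis == 1L) drugIds(Y) else proteinIds(Y)
  unitBuilder <- if (axis == 1L) drugKernel else proteinKernel
  partnerBuilder <- if (axis == 1L) proteinKernel else drugKernel
  if (.is_gip(unitBuilder)) stop("scenario violation")  # guarded upstream
  KunitFull <- kernelValues(unitBuilder$kernel)
  idxFull <- match(unitIds, kernelIds(unitBuilder$kernel))
  if (anyNA(idxFull)) stop("unit kernel missing required ids")
  KunitFull <- KunitFull[idxFull, idxFull, drop = FALSE]

  predRows <- list(); sel <- list()
  for (u in seq_len(nUnit)) {
    tr <- setdiff(seq_len(nUnit), u)
    innerFolds <- .with_seed(seed * 1000L + u, {
      perm <- sample(tr)
      split(perm, ceiling(seq_along(perm) / innerSize))
    })
    # score each grid combo over the inner folds
    gridScores <- NULL
    for (v in seq_along(innerFolds)) {
      innerTest <- innerFolds[[v]]
      innerTrain <- setdiff(tr, innerTest)
      sc <- .unit_fold_scores(vals, obs, S, axis, innerTrain, innerTest,
                              KunitFull, partnerBuilder, lambda)
      if (is.null(gridScores)) {
        gridScores <- sc
        gridScores$sse <- sc$sse
        gridScores$n <- sc$n
      } else {
        gridScores$sse <- gridScores$sse + sc$sse
        gridScores$n <- gridScores$n + sc$n
      }
    }
    rms <- sqrt(gridScores$sse / pmax(gridScores$n, 1L))
    k <- .tie_break_best(rms, gridScores$lambda)
    # refit on all training units with the selected grid point and predict
    # the held-out unit
    out <- .unit_fold_scores(vals, obs, S, axis, tr, u, KunitFull,
                             partnerBuilder, gridScores$lambda[k],
                             sigmaFixed = gridScores$sigma[k],
                             returnPred = TRUE)
    predRows[[u]] <- out$pred
    sel[[u]] <- data.frame(fold = u, unit_id = unitIds[u],
                           lambda = gridScores$lambda[k],
                           sigmaPartner = gridScores$sigma[k],
                           inner_rmse = rms[k], stringsAsFactors = FALSE)
  }
  predDf <- do.call(rbind, predRows)
  new("CVResult", scenario = scenario, predictions = predDf,
      selected = do.call(rbind, sel),
      pearson = cor(predDf$measured, predDf$predicted),
      rmse = sqrt(mean((predDf$measured - predDf$predicted)^2)),
      seed = as.integer(seed))
}

# Fit on training units, predict test units; returns per-grid-point SSE/n
# or (for a single grid point) the prediction table. axis = 1: units are
# drug rows; axis = 2: units are protein columns.
.unit_fold_scores <- function(vals, obs, S, axis, trainUnits, testUnits,
                              KunitFull, partnerBuilder, lambda,
                              sigmaFixed = NULL, returnPred = FALSE) {
  if (axis == 1L) {
    subVals <- vals[trainUnits, , drop = FALSE]
    subObs <- obs[trainUnits, , drop = FALSE]
    subS <- S
  } else {
    subVals <- vals[, trainUnits, drop = FALSE]
    subObs <- obs[, trainUnits, drop = FALSE]
    subS <- S[trainUnits, trainUnits, drop = FALSE]
  }
  Ysub <- bioactivityMatrix(subVals,
                            rownames(subVals) %||% paste0("d", seq_len(nrow(subVals))),
                            colnames(subVals) %||% paste0("p", seq_len(ncol(subVals))),
                            observed = subObs)
  Vimp <- affinityValues(imputeMissing(Ysub, subS))

  Kunit <- KunitFull[trainUnits, trainUnits, drop = FALSE]
  eUnit <- .eigs(Kunit)
  # partner kernel candidates (full partner axis)
  if (.is_gip(partnerBuilder)) {
    profiles <- if (axis == 1L) t(Vimp) else Vimp
    builder <- partnerBuilder
    if (!is.null(sigmaFixed) && is.finite(sigmaFixed))
      builder <- gipBuilder(sigmaFixed)
    candP <- .gip_candidates(builder, profiles)
  } else {
    partnerIds <- if (axis == 1L) colnames(vals) else rownames(vals)
    candP <- .fixed_candidate(partnerBuilder, partnerIds)
  }

  kTest <- KunitFull[testUnits, trainUnits, drop = FALSE]
  res <- list(lambda = numeric(), sigma = numeric(),
              sse = numeric(), n = integer())
  predTab <- NULL
  for (b in seq_along(candP)) {
    ePart <- .eigs(candP[[b]]$kernel)
    eD <- if (axis == 1L) eUnit else ePart
    eP <- if (axis == 1L) ePart else eUnit
    for (l in lambda) {
      ff <- .fold_fit(eD, eP, Vimp, l)
      A <- eP$U %*% ff$C %*% t(eD$U)            # proteins x drugs (of Vimp)
      if (axis == 1L) {
        # predict held-out drug rows against all proteins
        KPfull <- candP[[b]]$kernel
        P <- kTest %*% t(A) %*% t(KPfull)        # testUnits x nP
        om <- obs[testUnits, , drop = FALSE]
        truth <- vals[testUnits, , drop = FALSE]
      } else {
        # predict held-out protein columns for all drugs
        KDfull <- candP[[b]]$kernel
        P <- t(kTest %*% A %*% t(KDfull))        # nD x testUnits
        om <- obs[, testUnits, drop = FALSE]
        truth <- vals[, testUnits, drop = FALSE]
      }
      res$lambda <- c(res$lambda, l)
      res$sigma <- c(res$sigma, candP[[b]]$sigma)
      res$sse <- c(res$sse, sum((P[om] - truth[om])^2))
      res$n <- c(res$n, sum(om))
      if (returnPred) {
        cellIdx <- which(om, arr.ind = TRUE)
        if (axis == 1L) {
          dIdx <- testUnits[cellIdx[, 1L]]
          pIdx <- cellIdx[, 2L]
        } else {
          dIdx <- cellIdx[, 1L]
          pIdx <- testUnits[cellIdx[, 2L]]
        }
        predTab <- data.frame(
          drug_id = rownames(vals)[dIdx] %||% paste0("d", dIdx),
          protein_id = colnames(vals)[pIdx] %||% paste0("p", pIdx),
          measured = truth[om], predicted = P[om],
          fold = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  if (returnPred) list(pred = predTab, scores = res) else res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid selection on the full data followed by a final refit
#'
#' Selects the grid point (lambda and, for interaction-profile kernels, the
#' width) minimizing cross-validated RMSE on the full training data under
#' the stated scenario -- closed-form leave-one-entry-out for
#' "bioactivity_imputation", leave-five-units-out folds for "new_drug" /
#' "new_target" -- then refits on all observed entries after imputation.
#'
#' @inheritParams nestedLOOCV
#' @param scenario one of "bioactivity_imputation", "new_drug",
#'   "new_target".
#' @param innerSize units per fold for the unit-based scenarios.
#' @return A [KronRLSModel-class]; the chosen grid point is attached as
#'   attribute \code{"selected"}.
#' @export
selectAndRefit <- function(Y, drugKernel, proteinKernel,
                           scenario = c("bioactivity_imputation", "new_drug",
                                        "new_target"),
                           lambda = lambdaGrid(), proteinSimilarity = NULL,
                           innerSize = 5L, seed = 1L) {
  scenario <- match.arg(scenario)
  vals <- affinityValues(Y)
  obs <- observedMask(Y)
  nP <- ncol(vals)
  if (is.null(proteinSimilarity)) proteinSimilarity <- diag(1, nP)
  S <- as.matrix(proteinSimilarity)
  Yimp <- imputeMissing(Y, S)
  Vimp <- affinityValues(Yimp)

  candD <- if (.is_gip(drugKernel)) .gip_candidates(drugKernel, Vimp)
           else .fixed_candidate(drugKernel, drugIds(Y))
  candP <- if (.is_gip(proteinKernel)) .gip_candidates(proteinKernel, t(Vimp))
           else .fixed_candidate(proteinKernel, proteinIds(Y))

  if (scenario == "bioactivity_imputation") {
    ystar <- .loo_imputed_values(vals, obs, S)
    idx <- which(obs)
    yTrue <- vals[idx]
    yRepl <- ystar[idx]
    best <- NULL
    for (a in seq_along(candD)) {
      eD <- .eigs(candD[[a]]$kernel)
      for (b in seq_along(candP)) {
        eP <- .eigs(candP[[b]]$kernel)
        for (l in lambda) {
          ff <- .fold_fit(eD, eP, Vimp, l)
          pin <- ff$F[idx] + ff$H[idx] * (yRepl - Vimp[idx])
          r <- sqrt(mean((pin - yTrue)^2))
          if (is.null(best) || r < best$rmse ||
              (r == best$rmse && l > best$lambda)) {
            best <- list(rmse = r, lambda = l, a = a, b = b,
                         sigmaD = candD[[a]]$sigma, sigmaP = candP[[b]]$sigma)
          }
        }
      }
    }
  } else {
    axis <- if (scenario == "new_drug") 1L else 2L
    if (axis == 1L && .is_gip(drugKernel)) stop("scenario violation")
    if (axis == 2L && .is_gip(proteinKernel)) stop("scenario violation")
    nUnit <- dim(vals)[axis]
    folds <- .with_seed(seed, {
      perm <- sample(seq_len(nUnit))
      split(perm, ceiling(seq_along(perm) / innerSize))
    })
    unitBuilder <- if (axis == 1L) drugKernel else proteinKernel
    partnerBuilder <- if (axis == 1L) proteinKernel else drugKernel
    unitIds <- if (axis == 1L) drugIds(Y) else proteinIds(Y)
    KunitFull <- kernelValues(unitBuilder$kernel)
    iFull <- match(unitIds, kernelIds(unitBuilder$kernel))
    KunitFull <- KunitFull[iFull, iFull, drop = FALSE]
    agg <- NULL
    for (v in seq_along(folds)) {
      testU <- folds[[v]]
      trainU <- setdiff(seq_len(nUnit), testU)
      if (!length(trainU)) next
      sc <- .unit_fold_scores(vals, obs, S, axis, trainU, testU, KunitFull,
                              partnerBuilder, lambda)
      if (is.null(agg)) agg <- sc
      else { agg$sse <- agg$sse + sc$sse; agg$n <- agg$n + sc$n }
    }
    rms <- sqrt(agg$sse / pmax(agg$n, 1L))
    k <- .tie_break_best(rms, agg$lambda)
    sig <- agg$sigma[k]
    best <- list(rmse = rms[k], lambda = agg$lambda[k],
                 a = 1L, b = 1L, sigmaD = NA_real_, sigmaP = NA_real_)
    if (axis == 1L && .is_gip(proteinKernel)) best$sigmaP <- sig
    if (axis == 2L && .is_gip(drugKernel)) best$sigmaD <- sig
    # rebuild final candidates at the selected width
    if (.is_gip(proteinKernel))
      candP <- .gip_candidates(gipBuilder(best$sigmaP), t(Vimp))
    if (.is_gip(drugKernel))
      candD <- .gip_candidates(gipBuilder(best$sigmaD), Vimp)
  }

  KD <- kernelMatrix(candD[[best$a]]$kernel, ids = drugIds(Y),
                     normalized = FALSE, repair = FALSE)
  KP <- kernelMatrix(candP[[best$b]]$kernel, ids = proteinIds(Y),
                     normalized = FALSE, repair = FALSE)
  model <- kronrlsFit(KD, KP, Yimp, best$lambda)
  attr(model, "selected") <- best
  model
}

#' Fold plan for the New Drug-Target Pair scenario (experimental)
#'
#' Constructs leave-drug-and-target-out folds: disjoint random drug groups
#' crossed with disjoint random protein groups; a fold's test cells are the
#' intersections, and its training data excludes both the fold's drugs and
#' proteins entirely. Plan construction only -- no evaluation loop is wired
#' to it, since this doubly-cold setting is rarely exercised in practice and
#' the package reports no reference accuracy for it.
#'
#' @param drugIds,proteinIds axis labels.
#' @param nFolds number of groups per axis.
#' @param seed integer.
#' @return list of folds, each with \code{drugs} and \code{proteins}
#'   character vectors, with attribute \code{scenario = "new_pair"}.
#' @export
newPairFolds <- function(drugIds, proteinIds, nFolds = 5L, seed = 1L) {
  stopifnot(nFolds >= 2L, length(drugIds) >= nFolds,
            length(proteinIds) >= nFolds)
  .with_seed(seed, {
    dg <- split(sample(drugIds), rep_len(seq_len(nFolds), length(drugIds)))
    pg <- split(sample(proteinIds), rep_len(seq_len(nFolds), length(proteinIds)))
    folds <- lapply(seq_len(nFolds), function(k)
      list(drugs = sort(dg[[k]]), proteins = sort(pg[[k]])))
    structure(folds, scenario = "new_pair")
  })
}
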