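#' Pearson correlation between measured and predicted affinities
#'
#' Thin wrapper over [stats::cor()] kept as the package's named evaluation
#' primitive; requires at least two pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 pairs")
  cor(x, y)
}

#' Root mean squared error
#'
#' @param x,y numeric vectors of equal length (measured and predicted).
#' @return RMSE, >= 0.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sqrt(mean((x - y)^2))
}

#' ROC-AUC sweep over interaction thresholds
#'
#' Binarizes measured affinities at each threshold (\code{measured >=
#' threshold} labels the positives) and computes the area under the ROC
#' curve of the predicted scores by the rank (Mann-Whitney) method with
#' midranks for ties. Thresholds leaving a single class are skipped and
#' reported rather than counted as 0.5. The default grid is the 11
#' thresholds on [6, 8] pKi with step 0.2; a 21-point sweep with step 0.1
#' is \code{seq(6, 8, by = 0.1)}.
#'
#' @param measured,predicted numeric vectors of equal length.
#' @param thresholds numeric vector of binarization thresholds.
#' @return list with \code{aucByThreshold} (named numeric), \code{meanAuc},
#'   and \code{skipped} (degenerate thresholds).
#' @export
rocAucSweep <- function(measured, predicted, thresholds = seq(6, 8, by = 0.2)) {
  if (length(measured) != length(predicted)) stop("length mismatch")
  aucs <- numeric(0)
  skipped <- numeric(0)
  for (th in thresholds) {
    lab <- measured >= th
    n1 <- sum(lab)
    n0 <- sum(!lab)
    if (n1 == 0L || n0 == 0L) {
      skipped <- c(skipped, th)
      next
    }
    r <- rank(predicted)              # midranks average ties
    auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aucs <- c(aucs, setNames(auc, format(th)))
  }
  if (length(skipped))
    warning(sprintf("%d threshold(s) with a single class skipped: %s",
                    length(skipped), paste(format(skipped), collapse = ", ")))
  list(aucByThreshold = aucs,
       meanAuc = if (length(aucs)) mean(aucs) else NA_real_,
       skipped = skipped)
}

#' Hypergeometric off-target enrichment test
#'
#' Upper-tail probability of observing at least \code{hits} true targets
#' among \code{tested} predictions when \code{trueTargets} of
#' \code{population} proteins are actual targets: \eqn{P(X \ge hits)} under
#' Hypergeometric(population, trueTargets, tested), computed exactly via
#' [stats::phyper()].
#'
#' @param population total number of candidate proteins.
#' @param trueTargets assumed number of actual targets in the population.
#' @param tested number of predictions tested experimentally.
#' @param hits number of confirmed targets among those tested.
#' @return exact upper-tail probability.
#' @examples
#' # 4 of 7 predicted off-targets confirmed against a 138-kinase panel,
#' # assuming at most 18 true targets:
#' hypergeometricEnrichment(138, 18, 7, 4)
#' @export
hypergeometricEnrichment <- function(population, trueTargets, tested, hits) {
  stopifnot(hits >= 0, hits <= tested, tested <= population,
            trueTargets <= population, trueTargets >= 0)
  phyper(hits - 1, trueTargets, population - trueTargets, tested,
         lower.tail = FALSE)
}

#' Floor undetected bioactivities before scoring
#'
#' Assays report no interaction when the compound fails to inhibit at the
#' highest tested concentration; such entries (coded \code{NA}) are replaced
#' by the floor corresponding to that concentration (pIC50 4.9 for a
#' 12,500 nM top concentration). Measured entries are untouched.
#'
#' @param measured numeric vector; \code{NA} marks no-interaction entries.
#' @param floorValue replacement value (default 4.9).
#' @return numeric vector with no missing entries.
#' @export
applyFloor <- function(measured, floorValue = 4.9) {
  measured[is.na(measured)] <- floorValue
  measured
}

#' Full evaluation report
#'
#' Bundles Pearson correlation, RMSE and the multi-threshold ROC-AUC sweep
#' into an [EvaluationReport-class].
#'
#' @inheritParams rocAucSweep
#' @return An [EvaluationReport-class].
#' @export
evaluatePredictions <- function(measured, predicted,
                                thresholds = seq(6, 8, by = 0.2)) {
  sweep <- suppressWarnings(rocAucSweep(measured, predicted, thresholds))
  new("EvaluationReport",
      pearsonR = pearsonCorrelation(measured, predicted),
      rmse = rmse(measured, predicted),
      aucByThreshold = sweep$aucByThreshold,
      meanAuc = sweep$meanAuc,
      skippedThresholds = sweep$skipped,
      n = length(measured))
}
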