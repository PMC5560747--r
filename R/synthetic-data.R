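#' Configuration for the synthetic bilinear binding-affinity generator
#'
#' Defaults describe the fixture used throughout the test suite: a 40 x 30
#' compound-kinase map with a rank-3 latent bilinear affinity surface,
#' measurement noise of 0.3 pKi units, and 20\% of cells unmeasured --
#' a desk-scale analogue of sparse large-scale kinase inhibitor profiling
#' data (pKi values roughly between 4 and 10, a majority of cells filled,
#' drug/protein similarity structure correlated with affinity).
#'
#' @param nDrugs,nProteins axis sizes.
#' @param latentDim latent factor dimension of the bilinear surface.
#' @param noiseSD Gaussian measurement noise, pKi units.
#' @param missingFrac fraction of cells masked as unmeasured, in [0, 1).
#' @param nClustersDrugs,nClustersProteins number of latent clusters per
#'   axis; cluster structure is what makes fingerprints and sequences
#'   informative about affinity.
#' @param fingerprintBits fingerprint length B.
#' @param bitFlipRate per-bit mutation rate away from the cluster template.
#' @param seqLength protein sequence length.
#' @param mutationRate per-residue mutation rate away from the cluster
#'   ancestor sequence.
#' @param seed integer seed; all draws come from one generator seeded once.
#' @return list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nDrugs = 40L, nProteins = 30L, latentDim = 3L,
                            noiseSD = 0.3, missingFrac = 0.2,
                            nClustersDrugs = 4L, nClustersProteins = 3L,
                            fingerprintBits = 256L, bitFlipRate = 0.05,
                            seqLength = 120L, mutationRate = 0.1,
                            seed = 1L) {
  stopifnot(nDrugs >= 2L, nProteins >= 2L, latentDim >= 1L, noiseSD >= 0,
            missingFrac >= 0, missingFrac < 1, nClustersDrugs >= 1L,
            nClustersProteins >= 1L, fingerprintBits >= 1L,
            seqLength >= 1L)
  structure(as.list(environment()), class = "syntheticConfig")
}

#' Generate a synthetic drug-target bioactivity dataset
#'
#' Draws per-cluster latent factor centers with per-object jitter for both
#' axes, maps the bilinear surface into the pKi range via
#' \code{7 + 1.5 * tanh(<u_d, v_p>)} (a modeling choice keeping values in
#' the observed range of kinase profiling data), adds Gaussian measurement
#' noise, and masks cells uniformly at the configured missing rate.
#' Fingerprints are cluster-specific random bit templates with per-drug bit
#' flips, so Tanimoto similarity tracks latent proximity; sequences are
#' per-cluster random ancestors with per-protein point mutations, so
#' Smith-Waterman similarity tracks latent proximity on the protein side.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with \code{bioactivity} ([BioactivityMatrix-class]),
#'   \code{fingerprints} (list of drugIds, bits), \code{sequences}
#'   ([Biostrings::AAStringSet]), \code{groundTruth} (noise-free full
#'   matrix), \code{drugFactors}, \code{proteinFactors}, and the config.
#' @export
simulateBindingData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  .with_seed(config$seed, {
    dIds <- sprintf("drug%03d", seq_len(config$nDrugs))
    pIds <- sprintf("prot%03d", seq_len(config$nProteins))

    dClust <- rep_len(seq_len(config$nClustersDrugs), config$nDrugs)
    pClust <- rep_len(seq_len(config$nClustersProteins), config$nProteins)
    dCenters <- matrix(rnorm(config$nClustersDrugs * config$latentDim),
                       config$nClustersDrugs)
    pCenters <- matrix(rnorm(config$nClustersProteins * config$latentDim),
                       config$nClustersProteins)
    U <- dCenters[dClust, , drop = FALSE] +
      matrix(rnorm(config$nDrugs * config$latentDim, sd = 0.4),
             config$nDrugs)
    V <- pCenters[pClust, , drop = FALSE] +
      matrix(rnorm(config$nProteins * config$latentDim, sd = 0.4),
             config$nProteins)

    truth <- 7 + 1.5 * tanh(U %*% t(V))
    dimnames(truth) <- list(dIds, pIds)
    noisy <- truth + matrix(rnorm(length(truth), sd = config$noiseSD),
                            nrow(truth))
    mask <- matrix(runif(length(truth)) >= config$missingFrac, nrow(truth))
    vals <- noisy
    vals[!mask] <- NA_real_

    templates <- matrix(rbinom(config$nClustersDrugs * config$fingerprintBits,
                               1L, 0.3),
                        config$nClustersDrugs)
    bits <- templates[dClust, , drop = FALSE]
    flips <- matrix(runif(length(bits)) < config$bitFlipRate, nrow(bits))
    bits[flips] <- 1L - bits[flips]
    rownames(bits) <- dIds

    ancestors <- vapply(seq_len(config$nClustersProteins), function(k)
      paste(sample(.aa_standard, config$seqLength, replace = TRUE),
            collapse = ""), character(1L))
    seqs <- vapply(seq_len(config$nProteins), function(p) {
      chars <- strsplit(ancestors[pClust[p]], "")[[1L]]
      mut <- runif(length(chars)) < config$mutationRate
      chars[mut] <- sample(.aa_standard, sum(mut), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1L))
    names(seqs) <- pIds

    list(bioactivity = bioactivityMatrix(vals, dIds, pIds,
                                         observed = mask & !is.na(vals)),
         fingerprints = list(drugIds = dIds, bits = bits),
         sequences = Biostrings::AAStringSet(seqs),
         groundTruth = truth,
         drugFactors = U, proteinFactors = V,
         config = config)
  })
}

#' Scenario recovery experiment on synthetic data
#'
#' Runs nested leave-one-out cross-validation (Bioactivity Imputation
#' scenario; interaction-profile drug kernel with the quantile-rule width
#' grid, Smith-Waterman protein kernel) and nested leave-drug-out
#' cross-validation (New Drug scenario; Tanimoto fingerprint drug kernel,
#' generic string protein kernel) on one synthetic instance, and reports the
#' Pearson correlation per scenario together with whether the imputation
#' scenario beats the harder new-drug scenario -- the qualitative ordering
#' expected of the two designs.
#'
#' @param config a [syntheticConfig()] list.
#' @param lambda regularization grid.
#' @param gs a [gsParams()] list for the protein string kernel.
#' @return list with \code{loo}, \code{ldo} ([CVResult-class] objects),
#'   \code{looPearson}, \code{ldoPearson}, \code{orderingHolds}.
#' @export
recoveryExperiment <- function(config = syntheticConfig(),
                               lambda = lambdaGrid(), gs = gsParams()) {
  data <- simulateBindingData(config)
  Y <- data$bioactivity
  SP <- normalizedSWMatrix(data$sequences)
  KPsw <- linearKernel(SP)
  loo <- nestedLOOCV(Y, gipBuilder(), fixedKernel(KPsw), lambda = lambda,
                     proteinSimilarity = SP, seed = config$seed)
  KDtan <- linearKernel(tanimotoMatrix(data$fingerprints$bits))
  KPgs <- gsKernelMatrix(data$sequences, gs)
  ldo <- nestedLDOCV(Y, fixedKernel(KDtan), fixedKernel(KPgs),
                     lambda = lambda, proteinSimilarity = SP,
                     seed = config$seed)
  list(loo = loo, ldo = ldo,
       looPearson = cvPearson(loo), ldoPearson = cvPearson(ldo),
       orderingHolds = cvPearson(loo) > cvPearson(ldo))
}
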