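---
title: "Kronecker kernel regression for drug-target affinity prediction: models and methods"
author: "kronDTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kronecker kernel regression for drug-target affinity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kronDTI)
```

# The prediction problem

Kinase inhibitors are promiscuous: the ATP-binding pockets they target are
highly conserved, so a compound designed against one kinase usually binds
many others. Large profiling assays quantify this as a compound-by-kinase
matrix of binding affinities, reported as $pK_i = -\log_{10} K_i$ (molar):
higher means stronger binding. Such matrices are expensive to fill, so they
arrive sparse, and two practical questions follow:

1. **Bioactivity imputation** -- predict the unmeasured cells of a matrix
   whose drugs and proteins are all represented by at least some
   measurements.
2. **New drug** (and, symmetrically, **new target**) -- predict the full
   target profile of a compound (protein) with *no* measurements at all.

kronDTI treats both as regression on the quantitative affinities rather
than binary interaction classification.

# KronRLS

Given a drug kernel $K_D$ ($n_D \times n_D$) and a protein kernel $K_P$
($n_P \times n_P$), the pairwise kernel over compound-protein pairs is the
Kronecker product $K = K_D \otimes K_P$, and kernel ridge regression solves
$(K + \lambda I)\alpha = y$ with $\lambda > 0$ balancing training error
against model complexity. Materializing $K$ is infeasible beyond toy sizes
($N = n_D n_P$), but with eigendecompositions
$K_D = U_D \Sigma_D U_D^T$ and $K_P = U_P \Sigma_P U_P^T$ the solution is

$$
\alpha = \mathrm{vec}(U_P\, C\, U_D^T), \qquad
C = \left(U_P^T\, Y^T\, U_D\right) \oslash
    \left(\sigma_P \sigma_D^T + \lambda\right),
$$

with $\oslash$ elementwise division and $Y$ the drugs-by-proteins label
matrix. Predictions for a query pair described by its kernel similarities
$k_D$, $k_P$ to the training axes are $f(x) = k_P (U_P C U_D^T) k_D^T$.

**Orientation convention.** $Y$ is drugs $\times$ proteins; $C$ and
$A = U_P C U_D^T$ are proteins $\times$ drugs, and `dualVector()` stacks
the columns of $A$, so the protein index varies fastest -- exactly the
ordering of `kronecker(K_D, K_P)`. A regression test pins this orientation
against the explicit solver (`kronrlsSolveExplicit()`), which is kept in
the package purely as the small-scale reference path (it refuses problems
above 4096 pairs).

**Numerical choices.** Kernels are accepted as PSD up to a relative floor
of $-10^{-8}\lambda_{max}$; eigenvalues inside that band are clipped to
zero before forming $(\sigma_P\sigma_D^T + \lambda)^{-1}$, and matrices
below the floor trigger an explicit repair (eigenvalue clipping with a
warning) in `kernelMatrix()`. $\lambda$ must be strictly positive; the
default grid is `lambdaGrid()` = $2^{-15}, 2^{-13}, \dots, 2^{9}$ (13
log-spaced values), chosen as a wide conventional ridge grid and
configurable everywhere.

## Imputation

The eigendecomposition shortcut requires a complete $Y$. Missing cells are
pre-filled by `imputeMissing()` with the weighted row (compound) average:
the contribution of each observed protein in the row is weighted by its
similarity (normalized Smith-Waterman score) to the protein whose value is
missing. Degenerate cases fall back in order: non-positive weight sums use
the unweighted row mean; fully missing rows use the observed column mean,
then the global mean. Imputed cells keep `observed = FALSE` and are never
counted in performance statistics.

# Molecular descriptors as kernels

All kernels are positive semidefinite and cosine-normalized
($K'_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$; zero-diagonal entries map to 1 on
the diagonal and 0 elsewhere). Normalization is applied at the matrix
level; the raw generic-string pair values are left unnormalized.

* **Tanimoto fingerprint kernels** (`tanimotoMatrix()` + `linearKernel()`):
  the Tanimoto score $N_{11}/(N_i + N_j - N_{11})$ compares binary
  substructure fingerprints of any length (881, 1024, 166, 4860 bits, ...);
  the drug kernel is the linear kernel $S S^T$ on the rows of the score
  matrix. Two all-zero fingerprints score 1 (identity of indiscernibles);
  an all-zero against a non-empty fingerprint scores 0. Fingerprint
  *generation* is out of scope: fingerprints are consumed as tables.
* **Gaussian interaction-profile (GIP) kernels** (`gipKernel()`):
  $\exp(-\|v_i - v_j\|^2 / 2\sigma^2)$ on a molecule's vector of affinities
  across the partner axis (rows of the imputed $Y$ for drugs, columns for
  proteins). Candidate widths come from `sigmaGridFromDistances()`: the
  0.1/0.5/0.9 empirical quantiles (linear interpolation, `quantile()` type
  7) of the off-diagonal pairwise *Euclidean distances* -- distances, not
  squared distances, a choice surfaced here because either reading is
  defensible; the quantile levels then act as the grid dimension and the
  widths are recomputed inside every cross-validation fold.
* **Smith-Waterman kernels** (`normalizedSWMatrix()`, `swKernel()`): local
  alignment scores under BLOSUM50 with affine gaps, normalized as
  $SW(i,j)/\sqrt{SW(i,i)SW(j,j)}$. Gap penalties are open 10 / extend 0.5
  (a gap of length $L$ costs $10 + 0.5L$) -- the EMBOSS water defaults for
  BLOSUM50, adopted because no single canonical choice exists; both are
  exposed through `alignmentParams()`. Alignment itself is delegated to
  `Biostrings::pairwiseAlignment()` and cross-checked in the test suite
  against an independently written affine-gap dynamic program.
* **Extended target profiles, SW+** (`swPlusProfiles()`): instead of
  comparing the study's proteins only with each other, each target is
  described by its normalized SW similarities to a large external reference
  proteome, and the kernel is the linear kernel on those rectangular
  profiles. This gives global features: two kinases can look similar
  because they relate to the wider proteome similarly, even if their direct
  alignment is unremarkable. The reference set is a user-supplied FASTA;
  the test suite uses small generated references, not a proteome download.
* **Generic string (GS) kernels** (`gsKernel()`, `gsKernelMatrix()`):
  every substring of length $l \le L$ of one sequence is compared with
  every equal-length substring of the other, each comparison weighted by a
  positional Gaussian on the 0-based start offsets
  ($e^{-(i-j)^2/2\sigma_p^2}$) and a content Gaussian on the concatenated
  per-residue descriptor vectors ($e^{-\|\psi^l - \psi'^l\|^2/2\sigma_c^2}$).
  Descriptors $\psi(a)$ default to the residue's 20-entry BLOSUM50 row
  (`blosumDescriptorTable()`). The positional term lets biologically
  matching motifs align even when shifted -- useful when comparing full
  sequences, kinase domains, or ATP-pocket subsequences, which differ only
  in the sequence set supplied. Defaults $L = 2$, $\sigma_p = 1$,
  $\sigma_c = 10$ were fixed once as a moderate setting (short motifs,
  near-local positional matching, content Gaussian spanning typical
  BLOSUM row distances) and are grid-searchable. The implementation runs in
  $O(L\,|s|\,|s'|)$ via running diagonal sums of the residue-level distance
  matrix and is validated against a literal triple-loop oracle.
* **Imported 3D-structure similarities** (`similarityToKernel()`): any
  precomputed square score matrix (structure alignment energies, sequence
  identities) is self-normalized when its diagonal carries self-scores,
  then passed through the linear kernel. Computing the 3D alignments
  themselves is out of scope.
* **Identity protein kernel** (`identityProteinKernel()`): the fallback
  when protein features are unavailable; KronRLS then decouples into
  independent drug-side ridge regressions per protein column (verified in
  the tests).

# Leakage-safe nested cross-validation

Model selection and performance estimation use nested cross-validation;
the inner loop picks the grid point (always by lowest inner RMSE, ties
toward larger $\lambda$, i.e. the more conservative model), the outer loop
measures performance.

**LOO-CV / Bioactivity Imputation** (`nestedLOOCV()`): each observed entry
is held out in turn. Its cell is masked *before* imputation, and for GIP
kernels the held-out pair's partner column (row) is excluded from the
profiles, so the held-out label cannot reach the fold model through any
path -- a property asserted directly by sentinel-perturbation tests
(changing the held-out value changes nothing about that fold's
prediction). The inner loop is an exact closed-form leave-one-entry-out:
because the model is linear in the labels, replacing one training label
$y_c$ by its own leave-out imputed value $y^*_c$ changes the fitted value
at $c$ by exactly $h_c(y^*_c - y_c)$, with $h_c$ the Kronecker hat
diagonal (`hatDiagonal()`). This evaluates every inner fold at every grid
point without refitting. The fold kernels and the imputation are the
per-outer-fold ones; the secondary effect of an inner label on the imputed
values of *other* missing cells in its row is retained, a deliberate
first-order design: the inner label never enters its own prediction (the
requirement that matters for selection bias), and recomputing the full
imputation and GIP kernel for every inner entry would turn an $O(N)$ inner
sweep into $O(N^2)$ refits.

**LDO-CV / New Drug** (`nestedLDOCV()`): each compound is held out in
turn; its row *and column* are removed from the drug kernel before
training. Requesting a drug-side GIP kernel here is refused as a scenario
violation: a genuinely new compound has no interaction profile.
Protein-side GIP kernels are rebuilt per fold from training rows only.
Inner folds remove `innerSize = 5` compounds at a time; the number of
inner folds is not canonically fixed anywhere, so the package uses
$\lceil n_{train}/5 \rceil$ disjoint random folds (seeded), which touches
every training compound exactly once per grid point. Predictions for the
held-out compound use its kernel similarities to training compounds only.

**LTO-CV / New Target** (`nestedLTOCV()`) mirrors LDO on the protein axis
(protein-side GIP disallowed). The doubly-cold **new-pair** scenario is
provided as fold-plan construction only (`newPairFolds()`), flagged
experimental: no evaluation loop is wired to it, and no reference accuracy
exists for it here.

All CV output is bit-reproducible under a fixed seed; inner folds derive
their RNG stream from the seed and the outer fold index, so results do not
depend on execution order. Aggregate Pearson $r$ and RMSE are computed
over outer-fold predictions of *measured* values only.

# Evaluation statistics

`evaluatePredictions()` bundles Pearson correlation, RMSE, and a
multi-threshold ROC-AUC sweep: measured affinities are binarized at each
threshold (`>=` marks the positives -- the boundary is counted as
interacting), AUC uses midranks for ties, and thresholds leaving a single
class are skipped with a warning rather than counted as 0.5. The default
sweep is the 11 thresholds on $[6, 8]$ pKi with step 0.2; a finer
21-threshold sweep is `seq(6, 8, 0.1)`. `applyFloor()` maps undetected
interactions (NA) to the pIC50 of the assay's highest tested concentration
(default 4.9, i.e. 12,500 nM) before scoring.
`hypergeometricEnrichment()` gives the exact upper tail $P(X \ge hits)$
for confirmed off-targets among tested predictions; for 4 hits of 7 tested
against a 138-protein panel with at most 18 assumed true targets it is
about 0.0057.

# The synthetic generator, and what passing tests show

`simulateBindingData()` emulates the statistical shape of a sparse kinase
profiling matrix without any external data: cluster-structured latent
factors $u_d, v_p \in \mathbb{R}^3$ per axis, affinity surface
$pK_i = 7 + 1.5\tanh\langle u_d, v_p\rangle$ (a modeling choice that keeps
values inside the realistic 4-10 band), Gaussian measurement noise (0.3
pKi by default, a typical inter-assay scale), and uniform missingness (20%
by default). Fingerprints are cluster templates with per-bit flips and
sequences are cluster ancestors with point mutations, so Tanimoto and
Smith-Waterman similarities genuinely correlate with the latent structure
-- the assumption the whole method rests on.

The default instance is 40 drugs by 30 proteins: large enough that the
scenario contrast is stable, small enough that full nested LOO-CV (about a
thousand outer folds, each with its own imputation, GIP kernel and grid
search) runs in well under a minute. On this instance the recovery
experiment (`recoveryExperiment()`) reproduces the qualitative signature
of the two designs: imputation-scenario correlation around 0.9, new-drug
correlation lower by a clear margin, ordering stable across seeds.

What this does **not** show: synthetic clusters are cleaner than chemical
series, missingness is uniform rather than panel-structured, noise is
homoscedastic, and the bilinear surface is exactly the model family the
method can represent. Passing recovery tests therefore validates the
machinery (leakage control, selection, kernels, solver), not real-data
accuracy; accuracy on real kinase maps must be established on real data.

# Known limitations

* Dense eigendecompositions: fine to a few thousand objects per axis, not
  for web-scale screening.
* Single kernel pair per model; multiple kernel learning is out of scope.
* The inner LOO's first-order treatment of imputation coupling (above).
* The new-pair scenario is plan-construction only.
* Fingerprints, domain/pocket annotations and 3D similarity matrices are
  inputs, not computed here.
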