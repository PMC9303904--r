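---
title: "Methods: functional classification trees and forests in fctree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional classification trees and forests in fctree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctree)
```

## The model

`fctree` classifies subjects observed as curves. The data are `N` signals
`x_i(t)` on a shared, strictly increasing grid of `T` time points with a class
label per curve; irregular or per-subject grids are out of scope in this
version (the benchmark signals this package targets are regularly sampled, and
supporting sparse designs would require a conditional-expectation FPCA that we
deliberately do not attempt).

Classification proceeds in two stages.

**Stage 1 — feature extraction.** Either of two basis representations turns a
curve into a short feature vector:

* *Functional principal components.* With trapezoidal quadrature weights
  `w_j` on the grid and the pointwise sample mean `x̄`, the package solves the
  symmetric eigenproblem of `W^{1/2} Cov W^{1/2}` (where `Cov` is the `T × T`
  sample covariance of the curves and `W = diag(w)`) and maps eigenvectors
  back via `ξ = W^{-1/2} u`. This discretized-covariance construction keeps
  the eigenfunctions exactly orthonormal under the same quadrature the rest
  of the package uses, and is directly checkable against a dense-matrix
  oracle, which is why it was preferred over basis-coefficient FPCA. Scores
  are `ν_ik = Σ_j w_j (x_ij − x̄_j) ξ_k(t_j)`; on the training set their
  variance equals `λ_k`. Test curves are centered with the *training* mean
  and projected on the *training* eigenfunctions — re-estimating components
  on a test set would produce an incompatible basis.
* *B-splines.* An order-4 basis (configurable, order ≥ 2) with equally
  spaced interior knots and boundary knots repeated to the order; the
  coefficients come from an ordinary least-squares fit of each curve on the
  basis evaluation matrix. No roughness penalty is applied, so
  identifiability requires `S ≤ T`; a penalized fitter that would allow
  `S > T` is intentionally out of scope.

FPCA operates on the raw discretized values by default; nothing prevents
passing smoothed values (`evaluate_expansion()` wrapped in a `curve_set`)
when the signals are noisy — both paths are supported, raw is the default
because it adds no tuning decisions.

**Stage 2 — trees and forests.** `fct()` grows a CART classification tree on
the feature matrix; `frf()` grows a bootstrap ensemble of unpruned trees with
per-split feature subsampling; `fbg()` is the bagging special case
`mtry = P`. Prediction is by majority vote with vote fractions reported.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| `K` (components) | 15 | Low-variance components can still be highly discriminative, so no explained-variance cutoff is applied by default; `K` is a genuine hyperparameter. |
| `S`, `order` (B-splines) | `min(25, T)`, 4 | Cubic splines; `S` bounded by `T` for a determinate least-squares fit. |
| `criterion` | Gini | Entropy (natural log, `0·log 0 = 0`) available. |
| `minsplit`, `minbucket`, `cp` | 20, 7, 0.01 | Mirrors conventional CART tooling so single trees are comparable with standard practice. |
| `nfolds` | 10 | Stratified by class, seeded. |
| `ntree` | 100 | Votes stabilize well before this on the designs used in the tests. |
| `mtry` | `floor(sqrt(P))` | The classical random-forest convention; `mtry = P` reproduces bagging exactly. |
| forest tree controls | `minsplit = 2, minbucket = 1, cp = 0` | Ensemble trees are grown deep and never pruned; the ensemble averaging, not pruning, controls variance. |

## Numerical and algorithmic choices

* **One quadrature everywhere.** Every integral (inner products, L2
  distances, scores, eigenvalue normalization) uses the same trapezoidal
  weights, so identities that hold in exact arithmetic (orthonormality,
  score variance = eigenvalue, the ANOVA decomposition) hold on the grid to
  rounding error.
* **Eigenfunction sign.** Each `ξ_k` is flipped so its largest-magnitude
  element is positive. Signs are otherwise arbitrary, and unstable signs
  would change split thresholds between runs.
* **Eigenvalue truncation.** Eigenvalues below `1e-12 λ_1` are treated as
  numerical zeros; a dataset with no variability is rejected as degenerate
  rather than silently producing noise components.
* **Split search.** Candidate thresholds are midpoints between consecutive
  sorted distinct feature values; rows with value `< θ` go left, `≥ θ` right
  (a row exactly at the threshold goes right). Ties are broken by larger
  impurity decrease, then lower feature index, then smaller threshold —
  arbitrary but fixed, so identical inputs always give identical trees.
* **Leaf label ties** go to the class that sorts first, with a warning.
* **Pruning.** Weakest-link cost-complexity pruning on the misclassification
  risk scale. The selection penalty is the cross-validation minimizer over
  the geometric means of consecutive path penalties; ties prefer the larger
  penalty (smaller tree). `cp = 0` is defined to return the tree unchanged
  (collapse uses a strict inequality), `cp = Inf` collapses to the root.
  Grow-time `cp` acts as an rpart-style gate on the scaled impurity gain
  relative to the root impurity. The 1-SE rule is not used; plain CV-minimum
  keeps the selection criterion transparent.
* **Distances.** The L2 distance is normalized by the integrated weight, so
  constant weight rescaling cancels. The derivative semi-metric differentiates
  the spline expansion analytically and normalizes by the domain length. The
  FPC semi-metric is the Euclidean distance between score vectors — the form
  implied by orthonormal eigenfunctions; a per-component weighting (e.g. by
  eigenvalue) would be a different estimator and is not implemented.
* **Splitting curves.** The theoretical splitting curve of node `z` sums
  `threshold × basis function` over the *distinct* features on the root-to-`z`
  path; when a feature is split twice on one path the deepest threshold is
  the binding constraint at `z` and is the one used. The empirical splitting
  curve searches the *whole* training set (not the node's subset), comparing
  score vectors against the TSC's score coordinates — the path thresholds
  padded with zeros over the remaining components, which are exactly the
  TSC's coordinates in the orthonormal eigenbasis. Ties go to the lowest
  curve index.
* **Relative variability measures** (`relDEV`, `relFBGSS`, `relFBLSS`)
  divide one pointwise sum of squares by another. Where the denominator is
  zero the ratio is reported as 0 when the numerator is also zero and as a
  missing value otherwise, and a `mask` attribute flags those grid points;
  infinities are never emitted. The denominator of the pairwise relative
  FBLSS can legitimately vanish where group means coincide across leaves —
  the mask makes that visible instead of guessing an interpretation.
* **Reference leaves** for pairwise comparisons are ranked by the fraction
  of correct predictions (ties: larger leaf, then lower leaf number);
  `ranking = "size_accuracy"` offers the alternative of trading support
  against purity for users who prefer bigger reference leaves.
* **Reproducibility.** Every stochastic operation (bootstrap, per-split
  feature subsampling, fold assignment, permutations) draws from one seeded
  stream, and the caller's RNG state is restored afterwards. Models
  serialize to JSON with 17 significant digits, so a reloaded model predicts
  bit-identically.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` / `generate_curves()` produce
`x_i(t) = μ_c(t) + Σ_j z_ij ψ_j(t) + ε_i(t)`: a common heartbeat-like
Gaussian-bump baseline, class offsets along the first of a small set of
smooth components `ψ_j` (orthonormalized on the grid, so the generating
eigenstructure is known exactly), per-curve Gaussian amplitudes, and iid
measurement noise. The defaults — 100 curves per class on 100 grid points,
class offsets ±3 along `ψ_1`, amplitude standard deviations (1, 0.6, 0.3),
noise sd 0.25 — put the two classes about six within-class standard
deviations apart on the leading score, i.e. a leading-score overlap of
roughly 0.1%, comfortably inside the ≤ 1% separability regime the test
suite assumes. These values were fixed once, from that design target, when
the generator was written.

The generator emulates the *data regime* of short biomedical signals with
class-specific morphology: smooth low-rank structure plus noise on a common
grid. It does **not** emulate real electrophysiology — no QRS dynamics, no
heteroscedastic or autocorrelated noise, no warping/phase variation, no
label noise, no class imbalance. Tests passing on these fixtures therefore
demonstrate that the algorithms are implemented correctly and behave as the
theory predicts under a known model; they say nothing about clinical
accuracy on real recordings, which must be assessed on real data (the
optional `scripts/ecg_benchmark.R` does exactly that when the user supplies
the public ECG archives).

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` use deliberately desk-scale
designs, chosen as the smallest sizes at which each property is sharply
testable: closed-form FPCA on a 1001-point grid; 100 randomized leaves for
the ANOVA identity; 200 random instances (N ≤ 10, P ≤ 3) against an
exhaustive split-search oracle; a 200-tree forest at N = 200 for the
out-of-bag expectation `(1 − 1/N)^N ≈ e^{-1}`; and 20 replicates of the
end-to-end study (two classes of 100 curves, K = 5, 50 trees) for out-of-bag
accuracy and permutation-importance ranking. Eigenvalue recovery is judged
on the error averaged over five replicates at N = 500 because a single
eigenvalue estimate at that sample size still carries ~6% sampling noise.

## Known limitations

* Common-grid data only; no registration, warping, or missing-value
  reconstruction.
* Fourier and wavelet bases are not implemented.
* No surrogate splits or missing-feature handling in the trees; no
  regression trees — the outcome is categorical.
* Forests offer no proximity matrices or class weighting, and although
  execution is sequential, results are defined by the seed, not by any
  scheduling guarantee.
* The binary TP/FP/TN/FN specializations require exactly two classes; with
  more classes the general group-wise measures apply and confusion roles are
  omitted.
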