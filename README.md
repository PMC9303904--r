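# fctree

Functional classification trees and functional random forests for supervised
classification of biomedical signals — ECG beats, EEG traces, spirometry
curves, or any sample of signals observed on a common time grid — together
with interpretive tools that read the classification rules back in the time
domain.

## The method

Each subject contributes one curve `x_i(t)` sampled at `T` points. Working
with the raw `T`-dimensional vectors invites the curse of dimensionality, so
the curves are first re-expressed in a low-dimensional basis:

* **Functional principal components (data-driven basis).** The sample
  covariance operator is discretized with trapezoidal quadrature weights and
  eigen-decomposed; the curve `x_i` is summarized by its score vector
  `ν_ik = ⟨x_i − x̄, ξ_k⟩`, `k = 1..K`, where the eigenfunctions `ξ_k` are
  orthonormal and the eigenvalues `λ_k` are the score variances. New curves
  are projected onto the *training* eigenfunctions, never re-decomposed.
* **B-splines (fixed basis).** Each curve is fit by least squares on `S`
  B-spline basis functions `φ_s(t)` and summarized by its coefficient vector.

A **functional classification tree (FCT)** is a CART classification tree
grown on the `N × K` score matrix (or `N × S` coefficient matrix): at each
node the split `ν_ik < ν_0k` maximizing the Gini (or Shannon–Wiener entropy)
impurity decrease is chosen, and the tree is pruned by cost-complexity
pruning with stratified cross-validation. A **functional random forest
(FRF)** grows an ensemble of unpruned FCTs on bootstrap samples, drawing a
fresh random subset of `m` candidate features at every split (with `m` equal
to the number of features the procedure reduces exactly to functional
bagging); out-of-bag votes estimate the error and permutation of out-of-bag
feature values yields a mean-decrease-accuracy importance per component.

Because the features are basis coefficients, every split has a functional
reading. The package computes:

* **Theoretical splitting curves (TSC)** — the split thresholds on a node's
  root path combined with their basis functions, `Σ_k ν_0k ξ_k(t)`;
* **Empirical splitting curves (ESC)** — the training curve closest to the
  TSC (FPC semi-metric for score features, L2 distance for B-splines);
* **Leaf variability diagnostics** — per-leaf functional deviance `DEV(t)`,
  the between-group decomposition `FBGSS(t)` with its relative version
  (pointwise in `[0, 1]` by the functional ANOVA identity), between-leaf
  sums of squares `FBLSS_g(t)` for a single class across leaves or between a
  leaf and a reference leaf, and — for binary outcomes — the TP/FP/TN/FN
  roles of every leaf member with their group mean curves.

## Worked example

```r
library(fctree)
sim   <- generate_curves(synthetic_spec(n_per_class = 50), seed = 1)
train <- sim$curves
train
#> curve_set: 100 curves on 100 grid points over [0, 1]
#> classes: 1 (50), 2 (50)

pc <- fpca(train, K = 5)
pc
#> fpca: 5 components on 100 grid points
#> explained variance: 95.4%, 3.1%, 0.9%, 0.0%, 0.0%

tree <- fct(pc$scores, train$labels, feature_kind = "fpc")
tree <- prune(tree, pc$scores, train$labels, seed = 2)
tree
#> Functional classification tree (fpc features, gini impurity)
#> classes: 1, 2
#> root n=100 (0.50 0.50)
#>   FPC1 < 0.226: n=50 (0.00 1.00) -> leaf 1: 2
#>   FPC1 >= 0.226: n=50 (1.00 0.00) -> leaf 2: 1
```

The pruned tree separates the two classes with a single cut on the first
FPC score at the threshold 0.226: curves whose centered projection on
`ξ_1` falls below it go to leaf 1 (class 2), the rest to leaf 2 (class 1).
The ensemble and its interpretation:

```r
forest <- frf(pc$scores, train$labels, ntree = 50, seed = 3)
oe <- oob_error(forest, pc$scores, train$labels)
#> OOB accuracy: 1.000 (0 samples never out-of-bag)

permutation_importance(forest, pc$scores, train$labels, seed = 4)
#> [1]  0.4410  0.0001  0.0023 -0.0004  0.0037
```

Permuting the first score column costs the forest 44 accuracy points on its
out-of-bag votes; the remaining components are noise to the classifier. The
empirical splitting curve turns the root rule into an actual training curve
(`esc(tree, 1, pc, train)` names curve 4 here), and
`leaf_diagnostics(tree, train, positive = "1")` reports each leaf's class
counts, confusion roles and variability curves:

```r
leaf_diagnostics(tree, train, positive = "1")
#> leaf diagnostics for 2 leaves
#> leaf 1 (node 2): n=50, predicts 2, counts: 1=0 2=50, roles: TN=50
#> leaf 2 (node 3): n=50, predicts 1, counts: 1=50 2=0, roles: TP=50
```

## Command line

A thin shell over the same functions (also at `inst/cli/fctree.R`):

```sh
Rscript inst/cli/fctree.R simulate --out train.ts --seed 1
Rscript inst/cli/fctree.R fit --data train.ts --model forest --n-fpcs 5 --seed 2 --out bundle.json
Rscript inst/cli/fctree.R predict --bundle bundle.json --data train.ts --out pred.csv
Rscript inst/cli/fctree.R importance --bundle bundle.json --data train.ts --out imp.csv
```

Readers accept UCR/UEA `.ts` files and label-first whitespace/comma
delimited text (the common ECG benchmark layouts). Models serialize to JSON
with full double precision, so a reloaded model predicts identically.

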