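Package: fctree
Title: Functional Classification Trees and Functional Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supervised classification of biomedical signals represented as
    curves on a common time grid. Curves are converted to features either by
    functional principal component decomposition (FPC scores) or by B-spline
    basis expansion (coefficients); classification trees are grown on the
    feature matrix with Gini or Shannon-Wiener impurity and cost-complexity
    pruning, and ensembles (functional bagging and functional random forests)
    provide out-of-bag error estimates and permutation importance. Also
    implements interpretive diagnostics for fitted trees: theoretical and
    empirical splitting curves, functional deviance of leaves, functional
    between-group and between-leaf variance decompositions, and their
    true/false positive/negative specializations for binary outcomes.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
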