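# A small fitted pipeline shared by the splitting-curve tests.
make_fitted <- function(seed = 5, n_per_class = 30, K = 5) {
  d <- generate_curves(synthetic_spec(n_per_class = n_per_class, n_points = 60),
                       seed = seed)
  m <- fpca(d$curves, K = K)
  tr <- fct(m$scores, d$curves$labels,
            fct_control(minsplit = 5, minbucket = 2, cp = 0))
  list(d = d, m = m, tr = tr)
}

test_that("the theoretical splitting curve is threshold times eigenfunction", {
  f <- make_fitted()
  root <- f$tr$nodes[[1]]
  expect_false(root$is_leaf)
  curve <- tsc(f$tr, 1, f$m)
  expect_curve_equal(curve, root$threshold * f$m$efuns[root$feature, ])
  leaf_id <- which(vapply(f$tr$nodes, function(n) n$is_leaf, logical(1)))[1]
  expect_error(tsc(f$tr, leaf_id, f$m), "leaf")
})

test_that("a repeated feature on the path contributes its deepest threshold", {
  # hand-built tree: root splits feature 2 at -0.24, left child splits
  # feature 2 again at -5.3, then feature 9 would follow in a deeper rule
  nodes <- list(
    list(id = 1L, parent = NA_integer_, depth = 0L, is_leaf = FALSE, n = 4L,
         counts = c(2L, 2L), pred = 1L, members = 1:4, feature = 2L,
         threshold = -0.24, gain = 0.1, left = 2L, right = 3L, leaf = NA_integer_),
    list(id = 2L, parent = 1L, depth = 1L, is_leaf = FALSE, n = 2L,
         counts = c(1L, 1L), pred = 1L, members = 1:2, feature = 2L,
         threshold = -5.3, gain = 0.1, left = 4L, right = 5L, leaf = NA_integer_),
    list(id = 3L, parent = 1L, depth = 1L, is_leaf = TRUE, n = 2L,
         counts = c(1L, 1L), pred = 1L, members = 3:4, feature = NA_integer_,
         threshold = NA_real_, gain = NA_real_, left = NA_integer_,
         right = NA_integer_, leaf = 3L),
    list(id = 4L, parent = 2L, depth = 2L, is_leaf = TRUE, n = 1L,
         counts = c(1L, 0L), pred = 1L, members = 1L, feature = NA_integer_,
         threshold = NA_real_, gain = NA_real_, left = NA_integer_,
         right = NA_integer_, leaf = 1L),
    list(id = 5L, parent = 2L, depth = 2L, is_leaf = TRUE, n = 1L,
         counts = c(0L, 1L), pred = 2L, members = 2L, feature = NA_integer_,
         threshold = NA_real_, gain = NA_real_, left = NA_integer_,
         right = NA_integer_, leaf = 2L))
  tree <- structure(list(nodes = nodes, labels = c("D", "H"),
                         control = fct_control(), feature_kind = "fpc",
                         p = 9L), class = "fct")
  f <- make_fitted(K = 9, n_per_class = 20)
  curve <- tsc(tree, 2L, f$m)
  expect_curve_equal(curve, -5.3 * f$m$efuns[2, ])
  p <- attr(curve, "path")
  expect_identical(p$features, 2L)
  expect_identical(p$thresholds, -5.3)
})

test_that("the empirical splitting curve is the score-space nearest neighbor", {
  f <- make_fitted()
  e <- esc(f$tr, 1, f$m, f$d$curves)
  root <- f$tr$nodes[[1]]
  target <- numeric(f$m$K)
  target[root$feature] <- root$threshold
  d_all <- sqrt(colSums((t(f$m$scores) - target)^2))
  expect_identical(e$index, which.min(d_all))
  expect_true(all(e$distance <= d_all))
  expect_curve_equal(e$curve, f$d$curves$values[e$index, ])

  # a curve whose scores equal the padded thresholds is found at distance 0
  synth <- f$m$scores
  synth[7, ] <- target
  e0 <- esc(f$tr, 1, f$m, f$d$curves, scores = synth)
  expect_identical(e0$index, 7L)
  expect_equal(e0$distance, 0)
})

test_that("the B-spline empirical splitting curve minimizes the L2 distance", {
  g <- seq(0, 1, length.out = 50)
  b <- bspline_basis(g, nbasis = 6)
  set.seed(10)
  cs <- curve_set(matrix(rnorm(10 * 50), 10), grid = g,
                  labels = rep(c("a", "b"), 5))
  ex <- smooth_curves(cs, b)
  tr <- fct(coef(ex), cs$labels, fct_control(minsplit = 2, minbucket = 1, cp = 0),
            feature_kind = "bspline")
  if (!tr$nodes[[1]]$is_leaf) {
    e <- esc(tr, 1, b, cs)
    theo <- tsc(tr, 1, b)
    d_all <- apply(cs$values, 1, l2_distance, x2 = theo, grid = g)
    expect_identical(e$index, which.min(d_all))
  }
})

test_that("leaf deviance matches hand computations and is shift-invariant", {
  expect_identical(leaf_deviance(rbind(rep(7, 5))), rep(0, 5))
  expect_equal(leaf_deviance(rbind(rep(1, 4), rep(3, 4))), rep(2, 4))
  set.seed(6)
  vals <- matrix(rnorm(5 * 8), 5)
  shift <- matrix(rep(rnorm(8), each = 5), 5)
  expect_curve_equal(leaf_deviance(vals + shift), leaf_deviance(vals), 1e-10)
  expect_error(leaf_deviance(vals[0, ]), "empty leaf")
})

test_that("relative deviance is 1 for the root and 0 for singletons", {
  set.seed(9)
  vals <- matrix(rnorm(6 * 10), 6)
  expect_curve_equal(rel_leaf_deviance(vals, vals), rep(1, 10))
  expect_curve_equal(rel_leaf_deviance(vals[3, , drop = FALSE], vals),
                     rep(0, 10))
  # two constant curves split into singleton leaves: both relDEV 0
  root <- rbind(rep(1, 4), rep(3, 4))
  expect_curve_equal(rel_leaf_deviance(root[1, , drop = FALSE], root), rep(0, 4))
})

test_that("masked ratios implement the 0/0 and c/0 conventions", {
  r <- masked_ratio(c(0, 2, 3), c(0, 0, 6))
  expect_identical(as.numeric(r), c(0, NA, 0.5))
  expect_identical(attr(r, "mask"), c(TRUE, TRUE, FALSE))
})

test_that("FBGSS satisfies the functional ANOVA identity", {
  # singleton groups: between-group variability equals the whole deviance
  out <- fbgss(rbind(rep(1, 5), rep(3, 5)), c("A", "B"))
  expect_curve_equal(out$fbgss, rep(2, 5))
  expect_curve_equal(out$rel, rep(1, 5))
  expect_curve_equal(fbgss(matrix(rnorm(12), 3), rep("A", 3))$fbgss, rep(0, 4))

  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:15, 1); T <- sample(4:20, 1)
    vals <- matrix(rnorm(n * T), n)
    groups <- sample(letters[1:3], n, replace = TRUE)
    out <- fbgss(vals, groups)
    within <- Reduce(`+`, lapply(unique(groups), function(g)
      leaf_deviance(vals[groups == g, , drop = FALSE])))
    expect_curve_equal(out$fbgss + within, out$dev, 1e-8)
    ok <- !attr(out$rel, "mask")
    expect_true(all(out$rel[ok] >= -1e-12 & out$rel[ok] <= 1 + 1e-12))
  }
})

test_that("confusion roles follow the leaf's predicted class", {
  expect_identical(confusion_roles(c("+", "+", "-"), "+", positive = "+"),
                   c("TP", "TP", "FP"))
  expect_identical(confusion_roles(c("-", "-"), "-", positive = "+"),
                   c("TN", "TN"))
  expect_identical(confusion_roles(c("+", "-"), "-", positive = "+"),
                   c("FN", "TN"))
  expect_error(confusion_roles(c("a", "b", "c"), "a", positive = "a"),
               "binary")
})

test_that("between-leaves variability matches the worked example", {
  # group g: {0} in leaf 1 and {4, 4, 4} in leaf 2 -> overall mean 3,
  # FBLSS = 1*9 + 3*1 = 12
  vals <- rbind(rep(0, 6), rep(4, 6), rep(4, 6), rep(4, 6))
  lf <- c(1, 2, 2, 2); gr <- rep("g", 4)
  expect_curve_equal(fblss(vals, lf, gr, "g"), rep(12, 6))
  pair <- fblss_pair(vals, lf, gr, "g", 1, 2)
  expect_curve_equal(pair$fblss_pair, rep(12, 6))
  expect_curve_equal(pair$rel, rep(1, 6))
  # a group confined to one leaf has no between-leaf variability
  expect_curve_equal(fblss(vals, c(1, 1, 1, 1), gr, "g"), rep(0, 6))
  expect_error(fblss(vals, lf, gr, "absent"), "absent")
  expect_error(fblss_pair(vals, lf, gr, "g", 1, 3), "both leaves")
  # identical group means in both leaves give zero pair variability
  same <- rbind(rep(2, 6), rep(2, 6))
  expect_curve_equal(fblss_pair(same, c(1, 2), c("g", "g"), "g", 1, 2)$fblss_pair,
                     rep(0, 6))
})

test_that("per-leaf weighted deviations from the group mean cancel", {
  set.seed(20)
  vals <- matrix(rnorm(12 * 7), 12)
  lf <- sample(1:3, 12, replace = TRUE)
  gr <- rep("g", 12)
  overall <- colMeans(vals)
  acc <- 0
  for (l in unique(lf)) {
    rows <- which(lf == l)
    acc <- acc + length(rows) * (colMeans(vals[rows, , drop = FALSE]) - overall)
  }
  expect_curve_equal(acc, rep(0, 7), 1e-10)
})

test_that("the reference leaf maximizes accuracy with size tie-breaks", {
  leaf <- function(id, leafno, counts, pred) {
    list(id = id, parent = 1L, depth = 1L, is_leaf = TRUE, n = sum(counts),
         counts = counts, pred = pred, members = seq_len(sum(counts)),
         feature = NA_integer_, threshold = NA_real_, gain = NA_real_,
         left = NA_integer_, right = NA_integer_, leaf = leafno)
  }
  tree <- structure(list(nodes = list(
    list(id = 1L, parent = NA_integer_, depth = 0L, is_leaf = FALSE, n = 125L,
         counts = c(63L, 62L), pred = 1L, members = 1:125, feature = 1L,
         threshold = 0, gain = 0.1, left = 2L, right = 3L, leaf = NA_integer_),
    leaf(2L, 1L, c(19L, 1L), 1L),     # predicts c1 with purity 0.95
    leaf(3L, 2L, c(23L, 2L), 1L)),    # predicts c1 with purity 0.92
    labels = c("c1", "c2"), control = fct_control(), feature_kind = "fpc",
    p = 2L), class = "fct")
  expect_identical(select_reference_leaf(tree, "c1")$leaf, 1L)
  # equal purity: the larger leaf wins
  tree$nodes[[2]]$counts <- c(22L, 0L); tree$nodes[[2]]$n <- 22L
  tree$nodes[[3]]$counts <- c(63L, 0L); tree$nodes[[3]]$n <- 63L
  expect_identical(select_reference_leaf(tree, "c1")$leaf, 2L)
  expect_identical(select_reference_leaf(tree, "c1")$n, 63L)
  expect_error(select_reference_leaf(tree, "c2"), "no leaf predicts")
})

test_that("leaf diagnostics aggregate counts, roles and curves consistently", {
  f <- make_fitted(seed = 21)
  diag <- leaf_diagnostics(f$tr, f$d$curves, positive = "1")
  expect_s3_class(diag, "leaf_diagnostics")
  total_n <- sum(vapply(diag, function(r) r$n, integer(1)))
  expect_identical(total_n, nrow(f$d$curves$values))
  for (rec in diag) {
    expect_identical(sum(rec$counts), rec$n)
    expect_identical(length(rec$roles), rec$n)
    expect_curve_equal(rec$mean,
                       colMeans(f$d$curves$values[rec$members, , drop = FALSE]))
    expect_true(all(rec$fbgss <= rec$dev + 1e-10))
    if (rec$predicted == "1") expect_true(all(rec$roles %in% c("TP", "FP")))
    else expect_true(all(rec$roles %in% c("TN", "FN")))
  }
  tab <- diagnostics_table(diag)
  expect_named(tab, c("measure", "leaf", "t", "value", "mask"))
  expect_identical(nrow(tab),
                   length(diag) * 5L * length(f$d$curves$grid))
})

test_that("diagnostics are invariant to adding a common constant curve", {
  f <- make_fitted(seed = 33, n_per_class = 15)
  shifted <- curve_set(f$d$curves$values +
                         matrix(rep(sin(f$m$grid * 3), each = 30), 30),
                       f$d$curves$grid, f$d$curves$labels)
  d1 <- leaf_diagnostics(f$tr, f$d$curves)
  d2 <- leaf_diagnostics(f$tr, shifted)
  for (k in seq_along(d1)) {
    expect_curve_equal(d1[[k]]$dev, d2[[k]]$dev, 1e-8)
    expect_curve_equal(d1[[k]]$fbgss, d2[[k]]$fbgss, 1e-8)
  }
})
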