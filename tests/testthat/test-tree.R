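test_that("impurity measures match hand values and validate input", {
  expect_identical(gini(c(1, 0)), 0)
  expect_equal(gini(c(0.5, 0.5)), 0.5)
  expect_equal(gini(c(0.95, 0.05)), 0.095)
  expect_identical(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(rep(1 / 5, 5)), log(5))
  expect_error(gini(c(-0.1, 1.1)), "nonnegative")
  expect_error(gini(c(0.4, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(0.9, 0.2)), "sum to 1")
})

test_that("growing finds the exhaustive best split and stops on purity", {
  ctl <- fct_control(minsplit = 2, minbucket = 1, cp = 0)
  tr <- fct(matrix(c(-2, -1, 1, 2), ncol = 1), c(0, 0, 1, 1), ctl)
  root <- tr$nodes[[1]]
  expect_false(root$is_leaf)
  expect_equal(root$threshold, 0)
  expect_true(tr$nodes[[root$left]]$is_leaf && tr$nodes[[root$right]]$is_leaf)
  expect_identical(predict(tr, matrix(c(-2, -1, 1, 2), ncol = 1)),
                   c("0", "0", "1", "1"))

  # all labels identical: a depth-0 tree, not an error
  tr1 <- fct(matrix(rnorm(5), ncol = 1), rep("only", 5), ctl)
  expect_true(tr1$nodes[[1]]$is_leaf)
  expect_identical(unique(predict(tr1, matrix(0, 3, 1))), "only")

  # XOR-in-one-feature needs depth >= 2 but reaches training accuracy 1
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c("0", "1", "1", "0")
  tr2 <- fct(x, y, ctl)
  depth <- max(vapply(tr2$nodes, function(n) n$depth, integer(1)))
  expect_gte(depth, 2)
  expect_identical(predict(tr2, x), y)
  expect_error(fct(matrix(numeric(0), 0, 1), character(0)), "empty data")
})

test_that("the root split matches an independent exhaustive-search oracle", {
  set.seed(99)
  ctl <- fct_control(minsplit = 2, minbucket = 1, cp = 0)
  for (rep in 1:60) {
    N <- sample(4:10, 1); P <- sample(1:3, 1)
    x <- matrix(runif(N * P), N, P)
    y <- as.character(sample(1:2, N, replace = TRUE))
    if (length(unique(y)) < 2) next
    tr <- fct(x, y, ctl)
    orc <- oracle_root_split(x, y)
    root <- tr$nodes[[1]]
    if (is.null(orc)) { expect_true(root$is_leaf); next }
    expect_identical(root$feature, orc$feature)
    expect_equal(root$threshold, orc$threshold)
    expect_equal(root$gain, orc$gain, tolerance = 1e-12)
  }
})

test_that("accepted splits have strictly positive impurity decrease", {
  d <- separable_features(n_per_class = 30, p_noise = 3, seed = 5)
  tr <- fct(d$x, d$y, fct_control(minsplit = 4, minbucket = 2, cp = 0))
  gains <- vapply(Filter(function(n) !n$is_leaf, tr$nodes),
                  function(n) n$gain, numeric(1))
  expect_true(all(gains > 0))
})

test_that("unpruned trees with minbucket 1 memorize distinct rows", {
  set.seed(31)
  x <- matrix(runif(40), 20, 2)
  y <- as.character(sample(c("a", "b", "c"), 20, replace = TRUE))
  tr <- fct(x, y, fct_control(minsplit = 2, minbucket = 1, cp = 0))
  expect_identical(predict(tr, x), y)
  # training rows land in the leaves recorded at grow time
  ids <- predict(tr, x, type = "node")
  for (i in seq_len(20)) expect_true(i %in% tr$nodes[[ids[i]]]$members)
})

test_that("rows exactly at a threshold are routed right", {
  tr <- fct(matrix(c(-2, -1, 1, 2), ncol = 1), c(0, 0, 1, 1),
            fct_control(minsplit = 2, minbucket = 1, cp = 0))
  expect_identical(predict(tr, matrix(tr$nodes[[1]]$threshold)), "1")
  expect_error(predict(tr, matrix(0, 2, 3)), "width")
})

test_that("prune endpoints keep the full tree (cp 0) or only the root (cp Inf)", {
  d <- separable_features(n_per_class = 20, p_noise = 2, seed = 3)
  full <- fct(d$x, d$y, fct_control(minsplit = 4, minbucket = 2, cp = 0))
  same <- prune(full, cp = 0)
  expect_identical(lapply(same$nodes, `[`, c("is_leaf", "feature", "threshold")),
                   lapply(full$nodes, `[`, c("is_leaf", "feature", "threshold")))
  stump <- prune(full, cp = Inf)
  expect_length(stump$nodes, 1)
  expect_true(stump$nodes[[1]]$is_leaf)
})

test_that("pruned trees are nested in the full tree", {
  set.seed(8)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.character((x[, 1] > 0) + (runif(60) < 0.15))
  full <- fct(x, y, fct_control(minsplit = 4, minbucket = 2, cp = 0))
  pruned <- prune(full, x, y, nfolds = 5, seed = 11)
  # every split retained by pruning exists identically in the full tree
  splits <- function(tr)
    vapply(Filter(function(n) !n$is_leaf, tr$nodes),
           function(n) paste(n$feature, n$threshold, sep = "@"), character(1))
  expect_true(all(splits(pruned) %in% splits(full)))
  expect_lte(sum(vapply(pruned$nodes, function(n) n$is_leaf, logical(1))),
             sum(vapply(full$nodes, function(n) n$is_leaf, logical(1))))
})

test_that("cross-validated pruning removes splits on pure-noise features", {
  hits <- 0L
  for (seed in 1:20) {
    d <- separable_features(n_per_class = 30, p_noise = 3, gap = 5, seed = seed)
    full <- fct(d$x, d$y, fct_control(minsplit = 5, minbucket = 2, cp = 0))
    pruned <- prune(full, d$x, d$y, nfolds = 5, seed = seed)
    feats <- vapply(Filter(function(n) !n$is_leaf, pruned$nodes),
                    function(n) n$feature, integer(1))
    if (length(feats) > 0 && all(feats == 1)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 0.9 of 20 seeds keep only the informative feature
})

test_that("independent CART implementation agrees on the root split", {
  skip_if_not_installed("rpart")
  d <- separable_features(n_per_class = 40, p_noise = 2, gap = 3, seed = 13)
  tr <- fct(d$x, d$y, fct_control(minsplit = 20, minbucket = 7, cp = 0.01))
  df <- data.frame(y = factor(d$y), d$x)
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 20,
                                                    minbucket = 7, cp = 0.01,
                                                    maxsurrogate = 0,
                                                    maxcompete = 0, xval = 0))
  expect_identical(paste0("X", tr$nodes[[1]]$feature),
                   as.character(rp$frame$var[1]))
  expect_equal(tr$nodes[[1]]$threshold, rp$splits[1, "index"],
               tolerance = 1e-8)
})

test_that("tied leaf counts warn and predict the first sorted label", {
  x <- matrix(c(1, 2), ncol = 1)
  expect_warning(tr <- fct(x, c("b", "a"), fct_control(minsplit = 10)),
                 "tied")
  expect_identical(predict(tr, x), c("a", "a"))
})
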