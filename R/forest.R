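#' Fit a functional random forest (or functional bagging) ensemble
#'
#' Grows `ntree` unpruned classification trees, each on a bootstrap sample of
#' the rows drawn with replacement at the original size `N` (the in-bag
#' functional data, IBFD); the complement of each bootstrap sample is the tree's
#' out-of-bag set (OOBFD). At every split of every tree a fresh random subset
#' of `mtry` features is drawn as split candidates. With `mtry = ncol(x)` the
#' procedure reduces exactly to functional bagging (see [fbg()]). All
#' randomness comes from the single `seed`, so refits are bit-identical.
#'
#' @param x feature matrix `N x P` (FPC scores or B-spline coefficients).
#' @param y class labels, length `N`.
#' @param ntree number of trees `H`.
#' @param mtry features tried per split; default `floor(sqrt(P))` (classical
#'   random-forest convention), at least 1.
#' @param control tree-growing parameters; forest trees are grown deep and not
#'   pruned, so the default is `fct_control(minsplit = 2, minbucket = 1,
#'   cp = 0)`.
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @param feature_kind `"fpc"` or `"bspline"`, recorded on each tree.
#' @param bootstrap test hook: `"identity"` makes every tree see the original
#'   sample (no resampling, empty OOB), or a list of `ntree` index vectors to
#'   use as bootstrap samples. Default `NULL` draws standard bootstrap samples.
#' @return object of class `frf`: list with `trees`, `inbag` (list of index
#'   vectors), `oob` (complement index sets), `labels`, `mtry`, `ntree`,
#'   `seed`, `p`.
#' @export
frf <- function(x, y, ntree = 100L, mtry = max(1L, floor(sqrt(ncol(x)))),
                control = fct_control(minsplit = 2, minbucket = 1, cp = 0),
                seed = NULL, feature_kind = c("fpc", "bspline"),
                bootstrap = NULL) {
  feature_kind <- match.arg(feature_kind)
  x <- as.matrix(x)
  y <- as.character(y)
  N <- nrow(x); P <- ncol(x)
  ntree <- as.integer(ntree)
  mtry <- as.integer(mtry)
  if (ntree < 1) stop("ntree must be >= 1")
  if (mtry < 1 || mtry > P) stop("mtry must be in 1..", P)
  labels <- sort(unique(y))
  if (is.list(bootstrap) && length(bootstrap) != ntree)
    stop("bootstrap list must have one index vector per tree")
  fit <- with_seed(seed, {
    trees <- vector("list", ntree)
    inbag <- vector("list", ntree)
    for (h in seq_len(ntree)) {
      idx <- if (identical(bootstrap, "identity")) seq_len(N)
             else if (is.list(bootstrap)) as.integer(bootstrap[[h]])
             else sample.int(N, N, replace = TRUE)
      trees[[h]] <- fct(x[idx, , drop = FALSE], y[idx], control = control,
                        feature_kind = feature_kind, mtry = mtry)
      inbag[[h]] <- idx
    }
    list(trees = trees, inbag = inbag)
  })
  oob <- lapply(fit$inbag, function(idx) setdiff(seq_len(N), idx))
  structure(list(trees = fit$trees, inbag = fit$inbag, oob = oob,
                 labels = labels, mtry = mtry, ntree = ntree, seed = seed,
                 p = P, control = control, feature_kind = feature_kind),
            class = "frf")
}

#' Functional bagging
#'
#' Bootstrap aggregation of functional classification trees: the special case
#' of [frf()] in which every feature is a split candidate at every node
#' (`mtry = ncol(x)`), so the trees differ only through their bootstrap
#' samples.
#'
#' @inheritParams frf
#' @return an `frf` object with `mtry = ncol(x)`.
#' @export
fbg <- function(x, y, ntree = 100L,
                control = fct_control(minsplit = 2, minbucket = 1, cp = 0),
                seed = NULL, feature_kind = c("fpc", "bspline"),
                bootstrap = NULL) {
  frf(x, y, ntree = ntree, mtry = ncol(as.matrix(x)), control = control,
      seed = seed, feature_kind = feature_kind, bootstrap = bootstrap)
}

#' @export
print.frf <- function(x, ...) {
  kind <- if (x$mtry == x$p) "functional bagging" else "functional random forest"
  cat(kind, ": ", x$ntree, " trees, mtry = ", x$mtry, " of ", x$p,
      " features\n", sep = "")
  cat("classes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# votes: M x F count matrix from a subset of trees; returns list(pred, tie)
majority_vote <- function(counts, labels) {
  pred <- character(nrow(counts))
  tie <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    m <- max(counts[i, ])
    winners <- which(counts[i, ] == m)
    pred[i] <- labels[winners[1]]   # ties -> first label in sorted label set
    tie[i] <- length(winners) > 1
  }
  list(pred = pred, tie = tie)
}

#' Predict from a functional random forest
#'
#' Majority vote over the per-tree predictions. Ties are broken toward the
#' label that sorts first and flagged in the `"tie"` attribute.
#'
#' @param object a fitted [frf] model.
#' @param x feature matrix with `ncol(x)` equal to the training width.
#' @param type `"class"` for the voted labels, `"votes"` for the `M x F`
#'   matrix of vote fractions.
#' @param ... unused.
#' @return character vector of predicted labels with attributes `votes`
#'   (fraction matrix) and `tie` (logical), or the vote matrix itself.
#' @export
predict.frf <- function(object, x, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$p)
    stop("feature width ", ncol(x), " does not match training width ", object$p)
  F <- length(object$labels)
  counts <- matrix(0L, nrow(x), F, dimnames = list(NULL, object$labels))
  for (tr in object$trees) {
    pr <- match(predict(tr, x), object$labels)
    counts[cbind(seq_len(nrow(x)), pr)] <- counts[cbind(seq_len(nrow(x)), pr)] + 1L
  }
  fractions <- counts / object$ntree
  if (type == "votes") return(fractions)
  mv <- majority_vote(counts, object$labels)
  structure(mv$pred, votes = fractions, tie = mv$tie)
}

#' Out-of-bag error of a functional random forest
#'
#' Each training curve is predicted by majority vote over only the trees whose
#' bootstrap sample omitted it. Curves that are in-bag for every tree are
#' excluded from the error and counted.
#'
#' @param model a fitted [frf].
#' @param x,y the training features and labels.
#' @return list with `error` (misclassified fraction of OOB-covered samples),
#'   `predictions` (per-sample OOB votes, `NA` where never OOB),
#'   `n_never_oob`.
#' @export
oob_error <- function(model, x, y) {
  stopifnot(inherits(model, "frf"))
  x <- as.matrix(x); y <- as.character(y)
  N <- nrow(x)
  F <- length(model$labels)
  counts <- matrix(0L, N, F)
  for (h in seq_len(model$ntree)) {
    rows <- model$oob[[h]]
    if (length(rows) == 0) next
    pr <- match(predict(model$trees[[h]], x[rows, , drop = FALSE]),
                model$labels)
    counts[cbind(rows, pr)] <- counts[cbind(rows, pr)] + 1L
  }
  covered <- rowSums(counts) > 0
  if (!any(covered))
    stop("no OOB coverage: every sample is in-bag for every tree")
  preds <- rep(NA_character_, N)
  mv <- majority_vote(counts[covered, , drop = FALSE], model$labels)
  preds[covered] <- mv$pred
  list(error = mean(preds[covered] != y[covered]),
       predictions = preds,
       n_never_oob = sum(!covered))
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For every tree and every feature, the tree's accuracy on its out-of-bag
#' rows is compared with the accuracy after randomly permuting that feature's
#' out-of-bag values; the drops are averaged over trees. Features the forest
#' never relies on score approximately zero.
#'
#' @param model a fitted [frf].
#' @param x,y the training features and labels.
#' @param seed integer seed for the permutations.
#' @return numeric vector of length `P`: mean decrease in OOB accuracy per
#'   feature.
#' @export
permutation_importance <- function(model, x, y, seed = NULL) {
  stopifnot(inherits(model, "frf"))
  x <- as.matrix(x); y <- as.character(y)
  P <- ncol(x)
  with_seed(seed, {
    drops <- matrix(NA_real_, model$ntree, P)
    used <- 0L
    for (h in seq_len(model$ntree)) {
      rows <- model$oob[[h]]
      if (length(rows) == 0) next
      used <- used + 1L
      xo <- x[rows, , drop = FALSE]
      base_acc <- mean(predict(model$trees[[h]], xo) == y[rows])
      for (j in seq_len(P)) {
        xp <- xo
        xp[, j] <- xo[sample.int(length(rows)), j]
        drops[h, j] <- base_acc - mean(predict(model$trees[[h]], xp) == y[rows])
      }
    }
    if (used == 0L)
      stop("no OOB coverage: permutation importance needs out-of-bag rows")
    colMeans(drops, na.rm = TRUE)
  })
}
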