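#' Gini impurity of a class distribution
#'
#' `1 - sum(f^2)` over class fractions `f`; 0 for a pure node, at most
#' `1 - 1/F` for `F` classes.
#'
#' @param fractions nonnegative class proportions summing to 1.
#' @return scalar in `[0, 1 - 1/F]`.
#' @examples
#' gini(c(0.5, 0.5))   # 0.5
#' gini(c(1, 0))       # 0
#' @export
gini <- function(fractions) {
  check_fractions(fractions)
  1 - sum(fractions^2)
}

#' Shannon-Wiener entropy of a class distribution
#'
#' `-sum(f * log(f))` with natural logarithm and the convention
#' `0 * log(0) = 0`; 0 for a pure node, `log(F)` at the uniform distribution.
#'
#' @param fractions nonnegative class proportions summing to 1.
#' @return nonnegative scalar.
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # log(2)
#' @export
shannon_entropy <- function(fractions) {
  check_fractions(fractions)
  p <- fractions[fractions > 0]
  -sum(p * log(p))
}

check_fractions <- function(fractions) {
  if (any(fractions < 0)) stop("class fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  invisible(TRUE)
}

# impurity of count rows (matrix n_cuts x F), totals n (vector)
impurity_counts <- function(counts, n, criterion) {
  p <- counts / n
  if (criterion == "gini") {
    1 - rowSums(p^2)
  } else {
    lp <- ifelse(p > 0, log(p), 0)
    -rowSums(p * lp)
  }
}

#' Control parameters for growing a functional classification tree
#'
#' Defaults mirror the conventional CART tooling for classification so
#' single-tree results are comparable with standard practice: Gini impurity,
#' `minsplit = 20`, `minbucket = 7`, grow-time complexity gate `cp = 0.01`,
#' 10-fold cross-validation for pruning.
#'
#' @param criterion impurity criterion, `"gini"` or `"entropy"`.
#' @param minsplit minimum node size eligible for splitting.
#' @param minbucket minimum number of training rows in any child.
#' @param cp grow-time complexity gate: a split is accepted only if its
#'   impurity decrease, scaled by node share and relative to the root
#'   impurity, is at least `cp`.
#' @param maxdepth maximum tree depth (root = depth 0).
#' @param nfolds cross-validation folds used by [prune()].
#' @return a list of class `fct_control`.
#' @export
fct_control <- function(criterion = c("gini", "entropy"), minsplit = 20L,
                        minbucket = 7L, cp = 0.01, maxdepth = 30L,
                        nfolds = 10L) {
  criterion <- match.arg(criterion)
  stopifnot(minsplit >= 2, minbucket >= 1, cp >= 0, maxdepth >= 0, nfolds >= 2)
  structure(list(criterion = criterion, minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket), cp = cp,
                 maxdepth = as.integer(maxdepth), nfolds = as.integer(nfolds)),
            class = "fct_control")
}

# Best split of one feature vector. Returns NULL or
# list(threshold, gain, nl). Candidate thresholds are midpoints between
# consecutive sorted distinct values; within a feature, equal gains resolve to
# the smallest threshold.
best_split_feature <- function(v, y, F, minbucket, criterion) {
  n <- length(v)
  o <- order(v)
  vs <- v[o]; ys <- y[o]
  cuts <- which(vs[-n] < vs[-1])
  cuts <- cuts[cuts >= minbucket & (n - cuts) >= minbucket]
  if (length(cuts) == 0) return(NULL)
  cum <- vapply(seq_len(F), function(f) cumsum(ys == f), numeric(n))
  cum <- matrix(cum, nrow = n)
  tot <- cum[n, ]
  cL <- cum[cuts, , drop = FALSE]
  cR <- matrix(tot, length(cuts), F, byrow = TRUE) - cL
  nl <- cuts; nr <- n - cuts
  imp_parent <- impurity_counts(matrix(tot, 1), n, criterion)
  child <- (nl * impurity_counts(cL, nl, criterion) +
            nr * impurity_counts(cR, nr, criterion)) / n
  gain <- imp_parent - child
  best <- which.max(gain)           # first max = smallest threshold
  list(threshold = (vs[cuts[best]] + vs[cuts[best] + 1]) / 2,
       gain = gain[best], nl = nl[best])
}

# Best split over candidate features. Tie-break: larger gain, then lower
# feature index, then smaller threshold (handled inside best_split_feature).
best_split <- function(x, y, F, minbucket, criterion,
                       candidates = seq_len(ncol(x))) {
  best <- NULL
  for (j in sort(candidates)) {
    s <- best_split_feature(x[, j], y, F, minbucket, criterion)
    if (is.null(s)) next
    if (is.null(best) || s$gain > best$gain) {
      best <- s
      best$feature <- j
    }
  }
  best
}

new_node <- function(id, parent, depth, members, counts) {
  pred <- which.max(counts)
  list(id = id, parent = parent, depth = depth, is_leaf = TRUE,
       n = length(members), counts = counts, pred = pred,
       members = members, feature = NA_integer_, threshold = NA_real_,
       gain = NA_real_, left = NA_integer_, right = NA_integer_)
}

# Grow a CART tree. y is an integer class vector in 1..F. mtry < P triggers
# per-split feature subsampling from the current RNG stream (random-forest
# behaviour); mtry == P examines all features. Deterministic given inputs and
# RNG state.
grow_nodes <- function(x, y, F, control, mtry = ncol(x)) {
  N <- nrow(x)
  root_counts <- tabulate(y, nbins = F)
  root_imp <- impurity_counts(matrix(root_counts, 1), N, control$criterion)
  nodes <- list(new_node(1L, NA_integer_, 0L, seq_len(N), root_counts))
  open <- 1L
  while (length(open) > 0) {
    id <- open[1]; open <- open[-1]
    node <- nodes[[id]]
    rows <- node$members
    if (node$n < control$minsplit || node$depth >= control$maxdepth) next
    if (max(node$counts) == node$n) next                  # pure
    cand <- if (mtry < ncol(x)) sort(sample.int(ncol(x), mtry)) else seq_len(ncol(x))
    s <- best_split(x[rows, , drop = FALSE], y[rows], F, control$minbucket,
                    control$criterion, candidates = cand)
    if (is.null(s) || s$gain <= 0) next
    # rpart-style complexity gate relative to the root impurity
    if (root_imp > 0 && (node$n * s$gain) / (N * root_imp) < control$cp) next
    go_left <- x[rows, s$feature] < s$threshold
    lid <- length(nodes) + 1L; rid <- lid + 1L
    node$is_leaf <- FALSE
    node$feature <- s$feature; node$threshold <- s$threshold; node$gain <- s$gain
    node$left <- lid; node$right <- rid
    nodes[[id]] <- node
    nodes[[lid]] <- new_node(lid, id, node$depth + 1L, rows[go_left],
                             tabulate(y[rows[go_left]], nbins = F))
    nodes[[rid]] <- new_node(rid, id, node$depth + 1L, rows[!go_left],
                             tabulate(y[rows[!go_left]], nbins = F))
    open <- c(open, lid, rid)
  }
  nodes
}

# Assign leaf numbers 1..L in left-to-right (pre-order) traversal order.
assign_leaf_numbers <- function(nodes) {
  counter <- 0L
  walk <- function(id) {
    if (nodes[[id]]$is_leaf) {
      counter <<- counter + 1L
      nodes[[id]]$leaf <<- counter
    } else {
      nodes[[id]]$leaf <<- NA_integer_
      walk(nodes[[id]]$left)
      walk(nodes[[id]]$right)
    }
  }
  walk(1L)
  nodes
}

warn_leaf_ties <- function(nodes) {
  for (nd in nodes) {
    if (nd$is_leaf && sum(nd$counts == max(nd$counts)) > 1)
      warning("leaf ", nd$leaf, ": tied class counts; predicting the class ",
              "first in the sorted label set", call. = FALSE)
  }
  invisible(NULL)
}

#' Fit a functional classification tree
#'
#' Grows a CART classification tree on a feature matrix of functional
#' principal component scores (columns = components) or B-spline expansion
#' coefficients (columns = basis functions). At each node every candidate
#' feature is scanned; candidate thresholds are midpoints between consecutive
#' sorted distinct values and the split maximizing the weighted impurity
#' decrease is chosen. Rows with feature value `< threshold` go left, `>=`
#' goes right. Growing is deterministic given the inputs.
#'
#' @param x numeric feature matrix `N x P` (e.g. `fpca(train)$scores` or
#'   `coef(smooth_curves(train, basis))`).
#' @param y class labels, length `N` (coerced to character).
#' @param control a [fct_control()] list.
#' @param feature_kind `"fpc"` or `"bspline"`; recorded so interpretive tools
#'   know which basis system the columns refer to.
#' @param mtry number of features sampled (without replacement, from the
#'   current RNG stream) as split candidates at each node; default all
#'   features. Used by [frf()].
#' @return object of class `fct`: list with `nodes` (flat node table), sorted
#'   `labels`, `control`, `feature_kind`, `p` (feature count).
#' @examples
#' x <- matrix(c(-2, -1, 1, 2), ncol = 1)
#' y <- c("a", "a", "b", "b")
#' tr <- fct(x, y, fct_control(minsplit = 2, minbucket = 1, cp = 0))
#' predict(tr, x)
#' @export
fct <- function(x, y, control = fct_control(),
                feature_kind = c("fpc", "bspline"), mtry = NULL) {
  feature_kind <- match.arg(feature_kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0) stop("empty data")
  if (!all(is.finite(x))) stop("features must be finite")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("y must have one label per row of x")
  labels <- sort(unique(y))
  yi <- match(y, labels)
  if (is.null(mtry)) mtry <- ncol(x)
  if (mtry < 1 || mtry > ncol(x)) stop("mtry must be in 1..ncol(x)")
  nodes <- grow_nodes(x, yi, length(labels), control, mtry = mtry)
  nodes <- assign_leaf_numbers(nodes)
  obj <- structure(list(nodes = nodes, labels = labels, control = control,
                        feature_kind = feature_kind, p = ncol(x)),
                   class = "fct")
  warn_leaf_ties(nodes)
  obj
}

# Route feature rows down the tree; returns terminal node ids.
route_rows <- function(nodes, x) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    id <- 1L
    while (!nodes[[id]]$is_leaf) {
      id <- if (x[i, nodes[[id]]$feature] < nodes[[id]]$threshold)
        nodes[[id]]$left else nodes[[id]]$right
    }
    out[i] <- id
  }
  out
}

#' Predict classes (and terminal leaves) from a fitted tree
#'
#' @param object a fitted [fct] model.
#' @param x feature matrix with the same number of columns as at fit time.
#' @param type `"class"` for predicted labels, `"node"` for terminal node
#'   ids, `"leaf"` for leaf numbers (left-to-right 1..L).
#' @param ... unused.
#' @return character vector of labels, or integer vector of node/leaf ids.
#' @export
predict.fct <- function(object, x, type = c("class", "node", "leaf"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$p)
    stop("feature width ", ncol(x), " does not match training width ", object$p)
  ids <- route_rows(object$nodes, x)
  switch(type,
         class = object$labels[vapply(ids, function(i) object$nodes[[i]]$pred,
                                      integer(1))],
         node = ids,
         leaf = vapply(ids, function(i) object$nodes[[i]]$leaf, integer(1)))
}

#' @export
print.fct <- function(x, digits = 4, ...) {
  cat("Functional classification tree (", x$feature_kind, " features, ",
      x$control$criterion, " impurity)\n", sep = "")
  cat("classes:", paste(x$labels, collapse = ", "), "\n")
  fname <- function(j) paste0(if (x$feature_kind == "fpc") "FPC" else "BSP", j)
  walk <- function(id, indent, rule) {
    nd <- x$nodes[[id]]
    frac <- nd$counts / nd$n
    lab <- sprintf("%s n=%d (%s)", rule, nd$n,
                   paste(sprintf("%.2f", frac), collapse = " "))
    if (nd$is_leaf) {
      cat(strrep("  ", indent), lab, " -> leaf ", nd$leaf, ": ",
          x$labels[nd$pred], "\n", sep = "")
    } else {
      cat(strrep("  ", indent), lab, "\n", sep = "")
      walk(nd$left, indent + 1,
           sprintf("%s < %s:", fname(nd$feature), format(nd$threshold, digits = digits)))
      walk(nd$right, indent + 1,
           sprintf("%s >= %s:", fname(nd$feature), format(nd$threshold, digits = digits)))
    }
  }
  walk(1L, 0L, "root")
  invisible(x)
}

# ---- cost-complexity pruning -------------------------------------------------

# Misclassification risk (count scale) of each node and of the subtree below
# it; returns list with per-node R, subtree risk, subtree leaf count.
subtree_stats <- function(nodes) {
  n_ids <- length(nodes)
  R <- Rsub <- numeric(n_ids); leaves <- integer(n_ids)
  rec <- function(id) {
    nd <- nodes[[id]]
    R[id] <<- nd$n - max(nd$counts)
    if (nd$is_leaf) {
      Rsub[id] <<- R[id]; leaves[id] <<- 1L
    } else {
      rec(nd$left); rec(nd$right)
      Rsub[id] <<- Rsub[nd$left] + Rsub[nd$right]
      leaves[id] <<- leaves[nd$left] + leaves[nd$right]
    }
  }
  rec(1L)
  list(R = R, Rsub = Rsub, leaves = leaves)
}

live_internal_ids <- function(nodes) {
  ids <- vapply(nodes, function(nd)
    if (!nd$is_leaf && !isTRUE(nd$dead)) nd$id else NA_integer_, integer(1))
  ids[!is.na(ids)]
}

collapse_node <- function(nodes, id) {
  # turn internal node into a leaf, dropping (marking dead) its subtree
  drop <- function(i) {
    if (!nodes[[i]]$is_leaf) {
      drop(nodes[[i]]$left); drop(nodes[[i]]$right)
    }
    nodes[[i]]$dead <<- TRUE
  }
  nd <- nodes[[id]]
  drop(nd$left); drop(nd$right)
  nd$is_leaf <- TRUE
  nd$feature <- NA_integer_; nd$threshold <- NA_real_; nd$gain <- NA_real_
  nd$left <- NA_integer_; nd$right <- NA_integer_
  nodes[[id]] <- nd
  nodes
}

# remove dead nodes and renumber ids compactly (preserving structure)
compact_nodes <- function(nodes) {
  alive <- vapply(nodes, function(nd) !isTRUE(nd$dead), logical(1))
  old_ids <- which(alive)
  remap <- integer(length(nodes)); remap[old_ids] <- seq_along(old_ids)
  out <- vector("list", length(old_ids))
  for (k in seq_along(old_ids)) {
    nd <- nodes[[old_ids[k]]]
    nd$id <- k
    if (!is.na(nd$parent)) nd$parent <- remap[nd$parent]
    if (!nd$is_leaf) {
      nd$left <- remap[nd$left]; nd$right <- remap[nd$right]
    }
    nd$dead <- NULL
    out[[k]] <- nd
  }
  out
}

# Weakest-link sequence: data.frame of (alpha, n_leaves) for the nested
# subtree path, alpha on the per-sample risk scale (risk counts / N).
cc_path <- function(nodes, N) {
  alphas <- 0
  nl <- sum(vapply(nodes, function(nd) nd$is_leaf && !isTRUE(nd$dead), logical(1)))
  nleaves <- nl
  work <- nodes
  while (length(live_internal_ids(work)) > 0) {
    st <- subtree_stats(work)
    ids <- live_internal_ids(work)
    g <- (st$R[ids] - st$Rsub[ids]) / ((st$leaves[ids] - 1) * N)
    gmin <- min(g)
    for (id in ids[g <= gmin + 1e-12]) {
      if (!work[[id]]$is_leaf && !isTRUE(work[[id]]$dead))
        work <- collapse_node(work, id)
    }
    alphas <- c(alphas, gmin)
    nleaves <- c(nleaves,
                 sum(vapply(work, function(nd) nd$is_leaf && !isTRUE(nd$dead),
                            logical(1))))
  }
  data.frame(alpha = alphas, n_leaves = nleaves)
}

# Smallest subtree whose weakest links all have g >= alpha (strict-< collapse,
# so alpha = 0 leaves the tree unchanged and alpha = Inf keeps only the root).
prune_at <- function(nodes, alpha, N) {
  repeat {
    ids <- live_internal_ids(nodes)
    if (length(ids) == 0) break
    st <- subtree_stats(nodes)
    g <- (st$R[ids] - st$Rsub[ids]) / ((st$leaves[ids] - 1) * N)
    weak <- ids[g < alpha - 1e-12]
    if (length(weak) == 0) break
    gmin <- min(g[g < alpha - 1e-12])
    for (id in ids[g <= gmin + 1e-12]) {
      if (!nodes[[id]]$is_leaf && !isTRUE(nodes[[id]]$dead))
        nodes <- collapse_node(nodes, id)
    }
  }
  compact_nodes(nodes)
}

#' Cost-complexity pruning of a functional classification tree
#'
#' Computes the weakest-link cost-complexity sequence of the fitted tree
#' (misclassification risk scale) and, unless `cp` is given, selects the
#' complexity penalty minimizing cross-validated misclassification error over
#' that sequence (folds stratified by class, seeded); ties prefer the larger
#' penalty, i.e. the smaller tree. Returns the pruned subtree, whose nodes are
#' a subset of the full tree's nodes.
#'
#' @param tree a fitted [fct] model.
#' @param x,y the training features and labels used to grow `tree` (required
#'   for cross-validation; `x` is also used to re-grow fold trees).
#' @param cp optional fixed complexity penalty: `cp = 0` returns the tree
#'   unchanged, `cp = Inf` collapses it to the root.
#' @param nfolds number of stratified CV folds (default from the tree's
#'   control).
#' @param seed integer seed for the fold assignment.
#' @param ... unused.
#' @return the pruned `fct`, with the selected penalty in `$cp_selected` and
#'   the complexity path in `$cc_path`.
#' @export
prune <- function(tree, ...) UseMethod("prune")

#' @rdname prune
#' @export
prune.fct <- function(tree, x = NULL, y = NULL, cp = NULL, nfolds = NULL,
                      seed = 1L, ...) {
  N <- tree$nodes[[1]]$n
  path <- cc_path(tree$nodes, N)
  if (is.null(cp)) {
    if (is.null(x) || is.null(y))
      stop("x and y are required for cross-validated penalty selection")
    x <- as.matrix(x); y <- as.character(y)
    nfolds <- if (is.null(nfolds)) tree$control$nfolds else as.integer(nfolds)
    if (nfolds > nrow(x)) stop("nfolds exceeds the number of samples")
    # candidate penalties: geometric means of consecutive path alphas, plus
    # the endpoints (0 = full tree; beyond the last alpha = root-only tree)
    a <- sort(unique(path$alpha))
    cand <- unique(c(0, sqrt(a[-length(a)] * a[-1]),
                     if (max(a) > 0) 2 * max(a) else Inf))
    folds <- with_seed(seed, stratified_folds(y, nfolds))
    cv_err <- numeric(length(cand))
    for (f in seq_len(nfolds)) {
      tr_rows <- which(folds != f); te_rows <- which(folds == f)
      fold_tree <- fct(x[tr_rows, , drop = FALSE], y[tr_rows],
                       control = tree$control, feature_kind = tree$feature_kind)
      for (ci in seq_along(cand)) {
        pruned <- prune_fixed(fold_tree, cand[ci])
        pr <- predict(pruned, x[te_rows, , drop = FALSE])
        cv_err[ci] <- cv_err[ci] + sum(pr != y[te_rows])
      }
    }
    # minimum CV error; ties resolved toward the larger penalty (smaller tree)
    cp <- max(cand[cv_err == min(cv_err)])
  }
  out <- prune_fixed(tree, cp)
  out$cp_selected <- cp
  out$cc_path <- path
  out
}

prune_fixed <- function(tree, alpha) {
  nodes <- prune_at(tree$nodes, alpha, tree$nodes[[1]]$n)
  tree$nodes <- assign_leaf_numbers(nodes)
  tree
}

# class-stratified fold ids in 1..nfolds (uses current RNG stream)
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    folds[rows] <- rep_len(seq_len(nfolds), length(rows))
  }
  folds
}
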