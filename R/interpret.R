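# Split path from the root to node z (inclusive): ordered (feature, threshold)
# pairs of the internal nodes passed through. Where the same feature is split
# more than once on the path, the deepest threshold is the binding constraint
# and is the one retained for the splitting-curve sum.
split_path <- function(tree, node_id) {
  nd <- tree$nodes[[node_id]]
  if (nd$is_leaf) stop("node ", node_id, " is a leaf; splitting curves are ",
                       "defined for internal nodes")
  ids <- integer(0)
  id <- node_id
  while (!is.na(id)) {
    ids <- c(id, ids)
    id <- tree$nodes[[id]]$parent
  }
  feats <- vapply(ids, function(i) tree$nodes[[i]]$feature, integer(1))
  thrs <- vapply(ids, function(i) tree$nodes[[i]]$threshold, numeric(1))
  keep <- !duplicated(feats, fromLast = TRUE)   # deepest occurrence wins
  list(features = feats[keep], thresholds = thrs[keep],
       path_features = feats, path_thresholds = thrs)
}

basis_curves <- function(components, features) {
  if (inherits(components, "fpca")) {
    components$efuns[features, , drop = FALSE]
  } else if (inherits(components, "bspline_basis")) {
    t(components$eval[, features, drop = FALSE])
  } else stop("components must be an fpca model or a bspline_basis")
}

#' Theoretical splitting curve of an internal node
#'
#' The separation rule accumulated down to node `z`, expressed as a curve: the
#' sum over the distinct features on the root-to-`z` path of the split
#' threshold times the corresponding basis function (eigenfunction for FPC
#' features, B-spline for fixed-basis features). If a feature is split more
#' than once on the path, its deepest threshold is used.
#'
#' @param tree a fitted [fct].
#' @param node_id id of an internal node (1 = root).
#' @param components the [fpca] model or [bspline_basis] whose columns the
#'   tree's features refer to.
#' @return numeric curve on the component grid, with attribute `path` (the
#'   retained features and thresholds).
#' @export
tsc <- function(tree, node_id, components) {
  p <- split_path(tree, node_id)
  B <- basis_curves(components, p$features)
  curve <- as.numeric(p$thresholds %*% B)
  attr(curve, "path") <- p[c("features", "thresholds")]
  curve
}

#' Empirical splitting curve of an internal node
#'
#' The training curve closest to the theoretical splitting curve of node `z`.
#' For FPC features the distance is the FPC semi-metric between each training
#' curve's score vector and the TSC's score coordinates (the path thresholds,
#' zero-padded over the remaining components); for B-spline features it is the
#' L2 distance between each raw training curve and the TSC evaluated on the
#' grid. Ties resolve to the lowest curve index.
#'
#' @param tree a fitted [fct].
#' @param node_id id of an internal node.
#' @param components the [fpca] model or [bspline_basis] behind the features.
#' @param train_curves the training [curve_set] (the ESC "lives in" the
#'   training data).
#' @param scores training score matrix for the FPC case; defaults to the
#'   scores stored on the fpca model.
#' @return list with `index` (training curve index), `curve` (its values),
#'   `distance`, and `tsc` (the theoretical curve).
#' @export
esc <- function(tree, node_id, components, train_curves, scores = NULL) {
  stopifnot(inherits(train_curves, "curve_set"))
  theo <- tsc(tree, node_id, components)
  p <- attr(theo, "path")
  if (inherits(components, "fpca")) {
    if (is.null(scores)) scores <- components$scores
    target <- numeric(ncol(scores))
    target[p$features] <- p$thresholds
    d <- sqrt(colSums((t(scores) - target)^2))
  } else {
    d <- apply(train_curves$values, 1, l2_distance, x2 = theo,
               grid = train_curves$grid)
  }
  idx <- which.min(d)   # which.min takes the first = lowest index on ties
  list(index = idx, curve = train_curves$values[idx, ], distance = d[idx],
       tsc = theo)
}

#' Functional deviance of a leaf
#'
#' Pointwise sum of squared deviations of the member curves from their
#' functional mean: large values flag time intervals where the leaf's curves
#' disagree with each other, regardless of their class labels.
#'
#' @param values `n x T` matrix of the member curves.
#' @return length-`T` nonnegative curve.
#' @export
leaf_deviance <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) == 0) stop("empty leaf")
  ctr <- sweep(values, 2, colMeans(values))
  colSums(ctr^2)
}

#' Relative functional deviance of a leaf
#'
#' The leaf deviance divided pointwise by the deviance of the whole training
#' set (the root node); see [masked_ratio()] for the zero-denominator
#' convention.
#'
#' @param leaf_values `n x T` matrix of member curves.
#' @param root_values `N x T` matrix of all training curves.
#' @return length-`T` curve with attribute `mask`.
#' @export
rel_leaf_deviance <- function(leaf_values, root_values) {
  masked_ratio(leaf_deviance(leaf_values), leaf_deviance(root_values))
}

#' Functional between-group sum of squares within a leaf
#'
#' Decomposes a leaf's functional deviance by outcome class:
#' `FBGSS(t) = sum_g n_g (xbar_g(t) - xbar(t))^2` over the groups present in
#' the leaf. Pointwise, `FBGSS + sum_g within-group deviance = DEV` (the
#' functional ANOVA identity), so `relFBGSS = FBGSS / DEV` lies in `[0, 1]`
#' wherever the leaf deviance is positive.
#'
#' @param values `n x T` matrix of member curves.
#' @param groups length-`n` class labels of the members.
#' @return list with `fbgss`, `rel` (masked ratio to the leaf deviance),
#'   `dev`, `group_means` (one row per group), `group_n`.
#' @export
fbgss <- function(values, groups) {
  values <- as.matrix(values)
  if (nrow(values) == 0) stop("empty leaf")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(values))
  gm <- rowsum(values, groups) / as.vector(table(groups)[sort(unique(groups))])
  ng <- as.vector(table(groups)[rownames(gm)])
  ctr <- sweep(gm, 2, colMeans(values))
  out_fbgss <- colSums(ng * ctr^2)
  dev <- leaf_deviance(values)
  list(fbgss = out_fbgss, rel = masked_ratio(out_fbgss, dev), dev = dev,
       group_means = gm, group_n = stats::setNames(ng, rownames(gm)))
}

#' Confusion roles of the members of a leaf (binary outcome)
#'
#' For a binary label set, members of a leaf predicting the positive
#' ("disease") class are true positives or false positives; members of a leaf
#' predicting the other ("healthy") class are true negatives or false
#' negatives.
#'
#' @param labels true labels of the leaf members.
#' @param predicted the leaf's predicted class.
#' @param positive which label is the positive ("disease") class.
#' @return character vector of roles (`"TP"`, `"FP"`, `"TN"`, `"FN"`).
#' @export
confusion_roles <- function(labels, predicted, positive) {
  labels <- as.character(labels)
  lvls <- unique(c(labels, predicted, positive))
  if (length(lvls) > 2)
    stop("binary specialization: confusion roles require a two-class outcome")
  if (predicted == positive) {
    ifelse(labels == positive, "TP", "FP")
  } else {
    ifelse(labels == positive, "FN", "TN")
  }
}

#' Functional between-leaves sum of squares of one group across all leaves
#'
#' `FBLSS_g(t) = sum_l n_g^(l) (xbar_g^(l)(t) - xbar_g(t))^2`, where
#' `xbar_g(t)` is the overall mean of group `g` pooled over all leaves:
#' how differently the leaves portray the same original class. For a binary
#' outcome, taking `g` = the diseased class gives the TP-FN variant and `g` =
#' the healthy class the TN-FP variant.
#'
#' @param values `N x T` matrix of all training curves.
#' @param leaf_ids length-`N` terminal leaf assignment of each curve (e.g.
#'   `predict(tree, x, type = "leaf")`).
#' @param groups length-`N` class labels.
#' @param g the group whose between-leaf variability is wanted.
#' @return length-`T` nonnegative curve.
#' @export
fblss <- function(values, leaf_ids, groups, g) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  rows <- which(groups == g)
  if (length(rows) == 0) stop("group ", g, " is absent from every leaf")
  overall <- colMeans(values[rows, , drop = FALSE])
  out <- numeric(ncol(values))
  for (l in unique(leaf_ids[rows])) {
    lr <- rows[leaf_ids[rows] == l]
    out <- out + length(lr) *
      (colMeans(values[lr, , drop = FALSE]) - overall)^2
  }
  out
}

#' Functional between-leaves sum of squares of one group in two leaves
#'
#' Compares the portrait of group `g` in leaf `l` against a reference leaf
#' `l_star`:
#' `n_g^(l) (xbar_g^(l) - xbar_g*)^2 + n_g^(l*) (xbar_g^(l*) - xbar_g*)^2`,
#' where `xbar_g*` pools group `g` over the two leaves only. The relative
#' version divides by the all-leaves [fblss()] of the same group (masked where
#' that vanishes). With a binary outcome and `g` = diseased, comparing an
#' FN-containing leaf with the best TP leaf explains why those false negatives
#' were missed; `g` = healthy against the best TN leaf explains false
#' positives.
#'
#' @inheritParams fblss
#' @param l,l_star the leaf of interest and the reference leaf (values of
#'   `leaf_ids`).
#' @return list with `fblss_pair` and `rel` (masked ratio to the all-leaves
#'   FBLSS of group `g`).
#' @export
fblss_pair <- function(values, leaf_ids, groups, g, l, l_star) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  r1 <- which(groups == g & leaf_ids == l)
  r2 <- which(groups == g & leaf_ids == l_star)
  if (length(r1) == 0 || length(r2) == 0)
    stop("group ", g, " must be present in both leaves")
  pooled <- colMeans(values[c(r1, r2), , drop = FALSE])
  pair <- length(r1) * (colMeans(values[r1, , drop = FALSE]) - pooled)^2 +
          length(r2) * (colMeans(values[r2, , drop = FALSE]) - pooled)^2
  total <- fblss(values, leaf_ids, groups, g)
  list(fblss_pair = pair, rel = masked_ratio(pair, total))
}

#' Select the reference leaf for a class
#'
#' Among leaves predicting class `c`, picks the one with the highest fraction
#' of correct predictions; ties prefer the larger leaf, then the lower leaf
#' number. Alternatively (`ranking = "size_accuracy"`) leaves are ranked by
#' the product of size and accuracy, trading leaf support against purity.
#'
#' @param tree a fitted [fct].
#' @param class the predicted class the reference leaf must have.
#' @param ranking `"purity"` (default) or `"size_accuracy"`.
#' @return list with `node_id`, `leaf` (leaf number), `purity`, `n`.
#' @export
select_reference_leaf <- function(tree, class,
                                  ranking = c("purity", "size_accuracy")) {
  ranking <- match.arg(ranking)
  ci <- match(class, tree$labels)
  if (is.na(ci)) stop("unknown class: ", class)
  cand <- Filter(function(nd) nd$is_leaf && nd$pred == ci, tree$nodes)
  if (length(cand) == 0) stop("no leaf predicts class ", class)
  purity <- vapply(cand, function(nd) nd$counts[ci] / nd$n, numeric(1))
  n <- vapply(cand, function(nd) nd$n, numeric(1))
  leafno <- vapply(cand, function(nd) nd$leaf, integer(1))
  score <- if (ranking == "purity") purity else purity * n
  ord <- order(-score, -n, leafno)
  best <- cand[[ord[1]]]
  list(node_id = best$id, leaf = best$leaf,
       purity = best$counts[ci] / best$n, n = best$n)
}

#' Per-leaf functional diagnostics of a fitted tree
#'
#' Computes, for every terminal node, the member counts by class, the
#' functional mean, deviance and relative deviance, the between-group
#' decomposition (FBGSS/relFBGSS), and — for a binary outcome with a declared
#' positive class — the confusion role of every member and the role-group
#' means.
#'
#' Leaf membership is taken from the training indices stored at growing time,
#' so `curves` must be the training set the tree's features were derived from.
#'
#' @param tree a fitted [fct].
#' @param curves the training [curve_set] (with labels).
#' @param positive optional positive ("disease") label for the binary
#'   specialization.
#' @return list of class `leaf_diagnostics`: one record per leaf with fields
#'   `leaf`, `node_id`, `members`, `n`, `counts`, `predicted`, `mean`, `dev`,
#'   `rel_dev`, `fbgss`, `rel_fbgss`, `group_means`, and if `positive` is
#'   given, `roles` and `role_means`.
#' @export
leaf_diagnostics <- function(tree, curves, positive = NULL) {
  stopifnot(inherits(tree, "fct"), inherits(curves, "curve_set"))
  if (is.null(curves$labels)) stop("curves must carry class labels")
  X <- curves$values
  leaves <- Filter(function(nd) nd$is_leaf, tree$nodes)
  leaves <- leaves[order(vapply(leaves, function(nd) nd$leaf, integer(1)))]
  out <- lapply(leaves, function(nd) {
    vals <- X[nd$members, , drop = FALSE]
    labs <- curves$labels[nd$members]
    bg <- fbgss(vals, labs)
    rec <- list(leaf = nd$leaf, node_id = nd$id, members = nd$members,
                n = nd$n,
                counts = stats::setNames(nd$counts, tree$labels),
                predicted = tree$labels[nd$pred],
                mean = colMeans(vals),
                dev = bg$dev,
                rel_dev = rel_leaf_deviance(vals, X),
                fbgss = bg$fbgss, rel_fbgss = bg$rel,
                group_means = bg$group_means)
    if (!is.null(positive) && length(tree$labels) == 2) {
      roles <- confusion_roles(labs, rec$predicted, positive)
      rec$roles <- roles
      rec$role_means <- lapply(split(seq_along(roles), roles), function(rr)
        colMeans(vals[rr, , drop = FALSE]))
    }
    rec
  })
  structure(out, class = "leaf_diagnostics", grid = curves$grid,
            labels = tree$labels)
}

#' @export
print.leaf_diagnostics <- function(x, ...) {
  cat("leaf diagnostics for", length(x), "leaves\n")
  for (rec in x) {
    cat(sprintf("leaf %d (node %d): n=%d, predicts %s, counts: %s%s\n",
                rec$leaf, rec$node_id, rec$n, rec$predicted,
                paste(sprintf("%s=%d", names(rec$counts), rec$counts),
                      collapse = " "),
                if (!is.null(rec$roles))
                  paste0(", roles: ",
                         paste(sprintf("%s=%d", names(table(rec$roles)),
                                       as.integer(table(rec$roles))),
                               collapse = " "))
                else ""))
  }
  invisible(x)
}

#' Long-format table of the per-leaf diagnostic curves
#'
#' Flattens a [leaf_diagnostics] object into a tidy data frame with one row
#' per (measure, leaf, grid point), suitable for CSV export or plotting.
#'
#' @param diag a [leaf_diagnostics] object.
#' @return data.frame with columns `measure`, `leaf`, `t`, `value`, `mask`.
#' @export
diagnostics_table <- function(diag) {
  grid <- attr(diag, "grid")
  rows <- list()
  for (rec in diag) {
    for (m in c("mean", "dev", "rel_dev", "fbgss", "rel_fbgss")) {
      v <- rec[[m]]
      mask <- attr(v, "mask")
      if (is.null(mask)) mask <- rep(FALSE, length(grid))
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, leaf = rec$leaf, t = grid, value = as.numeric(v),
        mask = mask)
    }
  }
  do.call(rbind, rows)
}
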