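# Shared fixtures, all generated in code.

# rank-1 functional sample: x_i(t) = a_i sin(2*pi*t); one eigenfunction
# sqrt(2) sin(2*pi*t), scores a_i / sqrt(2).
rank1_sine <- function(n_points = 1001, a = c(-3, -1, 1, 3)) {
  g <- seq(0, 1, length.out = n_points)
  list(curves = curve_set(outer(a, sin(2 * pi * g)), grid = g), a = a, grid = g)
}

# two clearly separated classes in one feature column plus pure-noise columns
separable_features <- function(n_per_class = 25, p_noise = 2, gap = 4,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- cbind(c(rnorm(n_per_class, -gap / 2), rnorm(n_per_class, gap / 2)),
             matrix(rnorm(n * p_noise), n, p_noise))
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

# exhaustive-search oracle for the root split: plain double loop over features
# and midpoints, same tie-break order (gain, then feature, then threshold)
oracle_root_split <- function(x, y, minbucket = 1, criterion = "gini") {
  labs <- sort(unique(y))
  yi <- match(y, labs)
  F <- length(labs)
  imp <- function(rows) {
    p <- tabulate(yi[rows], F) / length(rows)
    if (criterion == "gini") 1 - sum(p^2)
    else { p <- p[p > 0]; -sum(p * log(p)) }
  }
  n <- length(yi)
  parent <- imp(seq_len(n))
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vs <- sort(unique(x[, j]))
    if (length(vs) < 2) next
    for (m in seq_len(length(vs) - 1)) {
      thr <- (vs[m] + vs[m + 1]) / 2
      L <- which(x[, j] < thr)
      if (length(L) < minbucket || n - length(L) < minbucket) next
      gain <- parent -
        (length(L) * imp(L) + (n - length(L)) * imp(setdiff(seq_len(n), L))) / n
      if (is.null(best) || gain > best$gain)
        best <- list(feature = j, threshold = thr, gain = gain)
    }
  }
  best
}

expect_curve_equal <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(as.numeric(actual) - as.numeric(expected))), tol)
}
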