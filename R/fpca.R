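#' Functional principal component decomposition
#'
#' Eigen-decomposition of the sample covariance operator of a curve set,
#' discretized with trapezoidal quadrature weights: with `W = diag(w)` the
#' symmetric eigenproblem `W^{1/2} Cov W^{1/2} u = lambda u` is solved and the
#' eigenfunctions recovered as `xi = W^{-1/2} u`, so that
#' `<xi_j, xi_k> = delta_jk` under the same quadrature. Scores are
#' `nu_ik = <x_i - xbar, xi_k>`; on the training set their sample variance
#' equals `lambda_k`.
#'
#' Each eigenfunction's sign is fixed by flipping it so that its element of
#' largest absolute value is positive; this makes downstream trees and split
#' thresholds reproducible. Eigenvalues below `1e-12 * lambda_1` are truncated
#' as numerical noise.
#'
#' @param curves a [curve_set] (raw discretized values; smoothed values from
#'   [evaluate_expansion()] may be wrapped in a `curve_set` and passed too).
#' @param K number of components to retain, `1 <= K <= min(N-1, T)`.
#'   Default 15.
#' @return object of class `fpca` with fields `grid`, `mean` (length `T`),
#'   `efuns` (`K x T`, eigenfunctions on the grid), `values` (eigenvalues
#'   `lambda_1..lambda_K`, non-increasing), `total_variance` (sum of ALL
#'   positive eigenvalues, for explained-variance proportions), `weights`
#'   (quadrature weights), `scores` (`N x K` training score matrix), `labels`.
#' @examples
#' g <- seq(0, 1, length.out = 201)
#' a <- c(-3, -1, 1, 3)
#' cs <- curve_set(outer(a, sin(2 * pi * g)), grid = g)
#' m <- fpca(cs, K = 1)
#' m$scores[, 1]          # ~ a / sqrt(2)
#' explained_variance(m)  # 1
#' @export
fpca <- function(curves, K = 15L) {
  stopifnot(inherits(curves, "curve_set"))
  X <- curves$values
  N <- nrow(X); T <- ncol(X)
  if (N < 2) stop("at least 2 curves are required")
  K <- as.integer(K)
  kmax <- min(N - 1L, T)
  if (K < 1 || K > kmax)
    stop("K must be between 1 and min(N-1, T) = ", kmax)
  w <- trapezoid_weights(curves$grid)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Cov <- crossprod(Xc) / (N - 1)
  sw <- sqrt(w)
  B <- Cov * tcrossprod(sw)          # W^{1/2} Cov W^{1/2}
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  lambda <- eig$values
  keep <- lambda > 1e-12 * max(lambda[1], .Machine$double.eps)
  if (!any(keep))
    stop("degenerate covariance: the curves have no variability")
  lambda <- lambda[keep]
  U <- eig$vectors[, keep, drop = FALSE]
  if (K > length(lambda))
    stop("K = ", K, " exceeds the covariance rank ", length(lambda),
         " (degenerate covariance beyond that order)")
  total_var <- sum(lambda)
  lambda <- lambda[seq_len(K)]
  U <- U[, seq_len(K), drop = FALSE]
  Xi <- U / sw                        # columns: eigenfunctions on the grid
  # deterministic sign: largest-|.| element of each eigenfunction positive
  for (k in seq_len(K)) {
    j <- which.max(abs(Xi[, k]))
    if (Xi[j, k] < 0) Xi[, k] <- -Xi[, k]
  }
  scores <- Xc %*% (w * Xi)           # nu_ik = sum_j w_j Xc_ij xi_k(t_j)
  structure(list(grid = curves$grid, mean = mu, efuns = t(Xi),
                 values = lambda, total_variance = total_var, weights = w,
                 K = K, scores = unname(scores), labels = curves$labels),
            class = "fpca")
}

#' @export
print.fpca <- function(x, ...) {
  cat("fpca:", x$K, "components on", length(x$grid), "grid points\n")
  pv <- explained_variance(x)
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * pv[seq_len(min(5, x$K))]), collapse = ", "),
      if (x$K > 5) "...", "\n")
  invisible(x)
}

#' Proportion of variance explained by each retained component
#'
#' @param model a fitted [fpca] object.
#' @return length-`K` vector `lambda_k / sum(all lambda)`.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "fpca"))
  model$values / model$total_variance
}

#' Project new curves onto a trained eigenbasis
#'
#' Test curves must be expressed in the component space estimated on the
#' training data: each new curve is centered with the TRAINING mean and its
#' scores computed as quadrature inner products with the training
#' eigenfunctions.
#'
#' @param model a fitted [fpca] object.
#' @param new_curves a [curve_set] observed on the model's grid.
#' @return `M x K` score matrix.
#' @export
project <- function(model, new_curves) {
  stopifnot(inherits(model, "fpca"), inherits(new_curves, "curve_set"))
  if (length(new_curves$grid) != length(model$grid) ||
      !isTRUE(all.equal(new_curves$grid, model$grid)))
    stop("grid mismatch; resample the new curves on the training grid first")
  Xc <- sweep(new_curves$values, 2, model$mean)
  unname(Xc %*% (model$weights * t(model$efuns)))
}

#' Reconstruct curves from scores
#'
#' Truncated expansion `xbar(t) + sum_k nu_ik xi_k(t)` using the first
#' `ncol(scores)` components.
#'
#' @param model a fitted [fpca] object.
#' @param scores `N x K'` score matrix with `K' <= K`.
#' @return `N x T` matrix of reconstructed curve values.
#' @export
reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "fpca"))
  scores <- as.matrix(scores)
  if (ncol(scores) > model$K)
    stop("score width ", ncol(scores), " exceeds the number of fitted components ",
         model$K)
  sweep(scores %*% model$efuns[seq_len(ncol(scores)), , drop = FALSE],
        2, model$mean, `+`)
}

#' @export
predict.fpca <- function(object, new_curves, ...) project(object, new_curves)
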