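#' Weighted L2 distance between two curves
#'
#' `sqrt( int (x1 - x2)^2 w dt / int w dt )` with trapezoidal quadrature. With
#' the default constant weight this is the L2 distance normalized by the
#' domain length, so constant rescaling of `w` does not change the value.
#'
#' @param x1,x2 numeric vectors on a common grid.
#' @param grid strictly increasing time points.
#' @param w optional strictly positive weight curve (default constant 1).
#' @return scalar distance.
#' @examples
#' g <- seq(0, 1, length.out = 1001)
#' l2_distance(g, rep(0, 1001), g)  # ~ sqrt(1/3)
#' @export
l2_distance <- function(x1, x2, grid, w = NULL) {
  if (length(x1) != length(x2) || length(x1) != length(grid))
    stop("x1, x2 and grid must have the same length")
  if (is.null(w)) w <- rep(1, length(grid))
  if (any(w <= 0)) stop("weight curve must be strictly positive")
  qw <- trapezoid_weights(grid)
  sqrt(sum(qw * (x1 - x2)^2 * w) / sum(qw * w))
}

#' Semi-metric of r-order derivatives
#'
#' Distance between two curves through their analytic spline derivatives:
#' `sqrt( (1/|T|) int (x1^(r) - x2^(r))^2 dt )` where `|T|` is the domain
#' length. At `r = 0` this coincides with the unweighted [l2_distance()].
#'
#' @param expansion a [basis_expansion] holding both curves (or more).
#' @param i,j row indices of the two curves to compare.
#' @param r derivative order, `0 <= r < order` of the basis.
#' @return scalar semi-metric value.
#' @export
derivative_semimetric <- function(expansion, i, j, r = 1L) {
  stopifnot(inherits(expansion, "basis_expansion"))
  r <- as.integer(r)
  if (r < 0 || r >= expansion$basis$order)
    stop("derivative order r must satisfy 0 <= r < basis order ",
         expansion$basis$order)
  grid <- expansion$grid
  dcoef <- expansion$coefs[i, , drop = FALSE] - expansion$coefs[j, , drop = FALSE]
  Phi_r <- eval_basis(expansion$basis, grid, deriv = r)
  d <- as.numeric(Phi_r %*% t(dcoef))
  qw <- trapezoid_weights(grid)
  sqrt(sum(qw * d^2) / (grid[length(grid)] - grid[1]))
}

#' Semi-metric of the functional principal component scores
#'
#' Euclidean distance between two K-dimensional score vectors. With
#' orthonormal eigenfunctions this equals the L2 distance between the rank-K
#' projections of the curves, hence it is a semi-metric on curve space (and a
#' proper metric on score space).
#'
#' @param s1,s2 numeric score vectors of equal length `K`.
#' @return scalar.
#' @examples
#' fpc_semimetric(c(3, 0), c(0, 4))  # 5
#' @export
fpc_semimetric <- function(s1, s2) {
  if (length(s1) != length(s2))
    stop("score vectors must have the same length")
  sqrt(sum((s1 - s2)^2))
}
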