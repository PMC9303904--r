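#' B-spline basis on an interval
#'
#' Builds a B-spline basis of a given order (degree + 1) with equally spaced
#' interior knots over `[a, b]` and boundary knots repeated to the order, and
#' caches its evaluation on a grid. Order 4 (cubic) is the conventional choice
#' for smooth biomedical signals.
#'
#' @param grid strictly increasing time points; the basis domain is
#'   `[min(grid), max(grid)]` and the evaluation cache is computed here.
#' @param nbasis number of basis functions `S` (must satisfy `S >= order`).
#' @param order spline order (polynomial degree + 1), `>= 2`; default 4.
#' @return object of class `bspline_basis` with fields `grid`, `order`,
#'   `nbasis`, `knots` (full knot vector) and `eval` (`T x S` matrix of
#'   `phi_s(t_j)`).
#' @export
bspline_basis <- function(grid, nbasis = min(25L, length(grid)), order = 4L) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  order <- as.integer(order)
  nbasis <- as.integer(nbasis)
  if (order < 2) stop("order must be >= 2")
  if (nbasis < order) stop("nbasis must be >= order")
  a <- grid[1]; b <- grid[length(grid)]
  n_interior <- nbasis - order
  interior <- if (n_interior > 0)
    seq(a, b, length.out = n_interior + 2)[-c(1, n_interior + 2)] else numeric(0)
  knots <- c(rep(a, order), interior, rep(b, order))
  obj <- structure(list(grid = grid, order = order, nbasis = nbasis,
                        knots = knots),
                   class = "bspline_basis")
  obj$eval <- eval_basis(obj, grid)
  obj
}

#' Evaluate basis functions (optionally a derivative) on points
#'
#' @param basis a [bspline_basis].
#' @param at evaluation points within the basis domain.
#' @param deriv derivative order (0 = the functions themselves); must be
#'   strictly less than the spline order.
#' @return `length(at) x S` matrix.
#' @export
eval_basis <- function(basis, at, deriv = 0L) {
  at <- as.numeric(at)
  a <- basis$knots[1]; b <- basis$knots[length(basis$knots)]
  tol <- 1e-10 * max(1, abs(b - a))
  if (any(at < a - tol | at > b + tol))
    stop("evaluation point outside basis domain [", a, ", ", b,
         "]; no extrapolation")
  at <- pmin(pmax(at, a), b)
  if (deriv >= basis$order)
    stop("derivative order ", deriv, " must be < spline order ", basis$order)
  splines::splineDesign(basis$knots, at, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(at)),
                        outer.ok = FALSE)
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("bspline_basis: S =", x$nbasis, "functions of order", x$order,
      "on [", format(x$grid[1]), ",", format(x$grid[length(x$grid)]), "]\n")
  invisible(x)
}

#' Least-squares basis expansion of a curve set
#'
#' Fits each curve by ordinary least squares onto the basis evaluation matrix,
#' giving the coefficient matrix `C` (`N x S`) used directly as features for
#' the fixed-basis classifier. No roughness penalty is applied, so
#' identifiability requires `S <= T`.
#'
#' @param curves a [curve_set].
#' @param basis a [bspline_basis] on the same grid.
#' @return object of class `basis_expansion` with fields `basis`, `coefs`
#'   (`N x S`), `grid`, `labels`.
#' @examples
#' g <- seq(0, 1, length.out = 30)
#' cs <- curve_set(rbind(g, g^2), grid = g)
#' be <- smooth_curves(cs, bspline_basis(g, nbasis = 6))
#' max(abs(evaluate_expansion(be) - cs$values))  # cubic splines fit these exactly
#' @export
smooth_curves <- function(curves, basis) {
  stopifnot(inherits(curves, "curve_set"), inherits(basis, "bspline_basis"))
  if (!isTRUE(all.equal(curves$grid, basis$grid)))
    stop("curve grid and basis grid differ; rebuild the basis on the data grid")
  Phi <- basis$eval
  if (basis$nbasis > length(curves$grid))
    stop("underdetermined fit: nbasis (", basis$nbasis,
         ") exceeds the number of grid points (", length(curves$grid), ")")
  qr_phi <- qr(Phi)
  if (qr_phi$rank < basis$nbasis)
    stop("singular design: basis evaluation matrix has rank ", qr_phi$rank,
         " < ", basis$nbasis)
  coefs <- t(qr.coef(qr_phi, t(curves$values)))
  structure(list(basis = basis, coefs = unname(coefs), grid = curves$grid,
                 labels = curves$labels),
            class = "basis_expansion")
}

#' Evaluate a basis expansion on a grid
#'
#' @param expansion a [basis_expansion].
#' @param at evaluation points within the basis domain (default: the fit grid).
#' @param deriv derivative order, `< order` of the basis.
#' @return `N x length(at)` matrix of evaluated (derivative) curves.
#' @export
evaluate_expansion <- function(expansion, at = expansion$grid, deriv = 0L) {
  stopifnot(inherits(expansion, "basis_expansion"))
  Phi <- eval_basis(expansion$basis, at, deriv = deriv)
  expansion$coefs %*% t(Phi)
}

#' @export
print.basis_expansion <- function(x, ...) {
  cat("basis_expansion:", nrow(x$coefs), "curves,", x$basis$nbasis,
      "B-spline coefficients each\n")
  invisible(x)
}

#' @export
coef.basis_expansion <- function(object, ...) object$coefs
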