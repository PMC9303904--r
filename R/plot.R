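# Minimal plotting conveniences (base graphics); decoration only.

#' Plot a curve set
#'
#' Draws all curves against the grid, colored by class label when present.
#'
#' @param x a [curve_set].
#' @param col optional per-class colors.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.curve_set <- function(x, col = NULL, ...) {
  if (!is.null(x$labels)) {
    lv <- sort(unique(x$labels))
    if (is.null(col)) col <- seq_along(lv) + 1
    cols <- col[match(x$labels, lv)]
  } else cols <- if (is.null(col)) 1 else col
  graphics::matplot(x$grid, t(x$values), type = "l", lty = 1, col = cols,
                    xlab = "t", ylab = "x(t)", ...)
  invisible(x)
}

#' Plot the eigenfunctions of a fitted FPCA
#'
#' @param x a fitted [fpca] model.
#' @param k which components to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fpca <- function(x, k = seq_len(x$K), ...) {
  graphics::matplot(x$grid, t(x$efuns[k, , drop = FALSE]), type = "l",
                    xlab = "t", ylab = expression(xi[k](t)), ...)
  pv <- round(100 * explained_variance(x)[k], 1)
  graphics::legend("topright", legend = sprintf("FPC %d (%.1f%%)", k, pv),
                   col = seq_along(k), lty = seq_along(k), cex = 0.7)
  invisible(x)
}
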