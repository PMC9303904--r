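#' Construct a set of discretely observed curves
#'
#' A `curve_set` holds `N` curves sampled on one shared, strictly increasing
#' time grid, optionally with a class label per curve. It is the raw functional
#' sample that every downstream step (smoothing, FPCA, trees, diagnostics)
#' consumes.
#'
#' @param values numeric matrix, `N x T`; row `i` is curve `x_i` evaluated on
#'   `grid`.
#' @param grid strictly increasing numeric vector of length `T` (time points,
#'   arbitrary units). Defaults to `0:(T-1)`.
#' @param labels optional vector of length `N` with the class of each curve;
#'   coerced to character.
#' @return an object of class `curve_set` with components `values`, `grid`,
#'   `labels` (possibly `NULL`).
#' @examples
#' cs <- curve_set(rbind(sin(seq(0, 1, length.out = 50)),
#'                       cos(seq(0, 1, length.out = 50))),
#'                 grid = seq(0, 1, length.out = 50), labels = c("a", "b"))
#' print(cs)
#' @export
curve_set <- function(values, grid = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- seq_len(ncol(values)) - 1
  grid <- as.numeric(grid)
  if (length(grid) != ncol(values))
    stop("grid length (", length(grid), ") must equal ncol(values) (",
         ncol(values), ")")
  if (length(grid) >= 2 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  if (!all(is.finite(values)))
    stop("curve values must be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("labels length (", length(labels), ") must equal the number of curves (",
           nrow(values), ")")
  }
  structure(list(values = values, grid = grid, labels = labels),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("curve_set: ", nrow(x$values), " curves on ", length(x$grid),
      " grid points over [", format(x$grid[1]), ", ",
      format(x$grid[length(x$grid)]), "]\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.curve_set <- function(x) dim(x$values)

#' Subset a curve set by curve index
#' @param x a [curve_set].
#' @param i integer or logical index over curves.
#' @param ... unused.
#' @return a `curve_set` with the selected curves.
#' @export
`[.curve_set` <- function(x, i, ...) {
  curve_set(x$values[i, , drop = FALSE], x$grid,
            if (!is.null(x$labels)) x$labels[i])
}

#' Trapezoidal quadrature weights for a grid
#'
#' All integrals in the package are approximated with the trapezoidal rule on
#' the observation grid; sharing a single weight routine keeps FPCA scores,
#' distances and variance decompositions numerically consistent.
#'
#' @param grid strictly increasing numeric vector.
#' @return numeric vector `w` such that `sum(w * f)` approximates
#'   the integral of `f` over the grid range.
#' @export
trapezoid_weights <- function(grid) {
  T <- length(grid)
  if (T == 1) return(1)  # degenerate: point mass
  d <- diff(grid)
  c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
}

#' Trapezoidal inner product of two curves
#'
#' Approximates `integral f(t) g(t) dt` over the grid range.
#'
#' @param f,g numeric vectors sampled on `grid`.
#' @param grid strictly increasing numeric vector of the same length.
#' @return scalar.
#' @examples
#' g <- seq(0, 1, length.out = 1001)
#' trapezoid_inner_product(g, g, g)  # ~ 1/3
#' @export
trapezoid_inner_product <- function(f, g, grid) {
  if (length(f) != length(g) || length(f) != length(grid))
    stop("f, g and grid must have the same length")
  sum(trapezoid_weights(grid) * f * g)
}

#' Pointwise functional mean of selected curves
#'
#' @param values `N x T` matrix of curve values.
#' @param member_idx indices of the rows to average (default all rows).
#' @return length-`T` mean curve.
#' @export
functional_mean <- function(values, member_idx = seq_len(nrow(values))) {
  values <- as.matrix(values)
  if (length(member_idx) == 0) stop("empty group: cannot average zero curves")
  colMeans(values[member_idx, , drop = FALSE])
}

#' Read curves from a file
#'
#' Supports the UCR/UEA `.ts` format (header lines starting with `@`, a
#' `@data` section with comma-separated values and a `:`-separated class
#' label) and label-first delimited text in the ECG200/ECG5000 layout (first
#' column = class label, remaining columns = the signal), whitespace- or
#' comma-separated.
#'
#' @param path file path.
#' @param format one of `"ts"`, `"tsv"`, `"csv"`. Default guesses from the
#'   file extension (`.ts` -> ts, `.csv` -> csv, otherwise tsv).
#' @return a [curve_set] with `grid = 0:(T-1)` and parsed labels.
#' @export
read_curves <- function(path, format = c("auto", "ts", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ts = "ts", csv = "csv", "tsv")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  if (format == "ts") {
    cs <- parse_ts_lines(lines, path)
  } else {
    sep_split <- if (format == "csv") "," else "[,[:space:]]+"
    rows <- lapply(seq_along(lines), function(i) {
      cells <- strsplit(trimws(lines[i]), sep_split)[[1]]
      cells <- cells[nzchar(cells)]
      vals <- suppressWarnings(as.numeric(cells[-1]))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1] + 1L
        stop("non-numeric cell at row ", i, ", column ", bad, " of ", path)
      }
      list(label = cells[1], values = vals)
    })
    lens <- vapply(rows, function(r) length(r$values), integer(1))
    if (length(unique(lens)) != 1)
      stop("unequal lengths: series lengths ", paste(unique(lens), collapse = ", "),
           "; a common grid is required")
    cs <- curve_set(do.call(rbind, lapply(rows, `[[`, "values")),
                    labels = vapply(rows, `[[`, character(1), "label"))
  }
  message(sprintf("read_curves: N=%d curves, T=%d points%s", nrow(cs$values),
                  length(cs$grid),
                  if (is.null(cs$labels)) "" else
                    paste0(", classes: ",
                           paste(sprintf("%s=%d", names(table(cs$labels)),
                                         as.integer(table(cs$labels))),
                                 collapse = " "))))
  cs
}

parse_ts_lines <- function(lines, path) {
  is_header <- startsWith(trimws(lines), "@")
  data_at <- which(tolower(trimws(lines)) == "@data")
  if (length(data_at) == 0) stop("no @data section in ", path)
  body <- lines[(data_at[1] + 1):length(lines)]
  body <- body[!startsWith(trimws(body), "@")]
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(trimws(body[i]), ":", fixed = TRUE)[[1]]
    label <- if (length(parts) > 1) trimws(parts[length(parts)]) else NA_character_
    series <- paste(parts[-length(parts)], collapse = ":")
    if (length(parts) == 1) series <- parts[1]
    vals <- suppressWarnings(as.numeric(strsplit(series, ",", fixed = TRUE)[[1]]))
    if (anyNA(vals))
      stop("non-numeric value in @data row ", i, " of ", path)
    list(label = label, values = vals)
  })
  lens <- vapply(rows, function(r) length(r$values), integer(1))
  if (length(unique(lens)) != 1)
    stop("unequal lengths in .ts data of ", path)
  labels <- vapply(rows, `[[`, character(1), "label")
  if (all(is.na(labels))) labels <- NULL
  curve_set(do.call(rbind, lapply(rows, `[[`, "values")), labels = labels)
}

#' Write curves to a file
#'
#' Inverse of [read_curves()]; round-trips exactly for both formats (values
#' are written with full double precision).
#'
#' @param curves a [curve_set] with labels.
#' @param path output file path.
#' @param format `"ts"`, `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, format = c("ts", "tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(curves, "curve_set"))
  labels <- curves$labels
  if (is.null(labels)) labels <- rep("0", nrow(curves$values))
  num <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
  if (format == "ts") {
    header <- c("@problemName fctree_export",
                "@timeStamps false",
                "@univariate true",
                paste("@classLabel true", paste(sort(unique(labels)), collapse = " ")),
                "@data")
    body <- vapply(seq_len(nrow(curves$values)), function(i) {
      paste0(paste(num(curves$values[i, ]), collapse = ","), ":", labels[i])
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    body <- vapply(seq_len(nrow(curves$values)), function(i) {
      paste(c(labels[i], num(curves$values[i, ])), collapse = sep)
    }, character(1))
    writeLines(body, path)
  }
  invisible(path)
}
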