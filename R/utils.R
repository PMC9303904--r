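# Evaluate code under a temporary RNG state; NULL seed uses the current
# stream. Restores (or removes) .Random.seed afterwards so callers' RNG state
# is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Pointwise ratio of two curves with a mask for zero denominators
#'
#' Relative variability measures divide one pointwise sum of squares by
#' another; where the denominator vanishes the ratio is undefined. The
#' convention used throughout the package: `0/0` is reported as 0,
#' `c/0` (`c > 0`) as `NA`, and an attached logical attribute `mask` flags all
#' grid points where the denominator was 0.
#'
#' @param num,den numeric vectors of equal length (both nonnegative).
#' @return `num/den` with the above convention and attribute `mask`.
#' @export
masked_ratio <- function(num, den) {
  if (length(num) != length(den)) stop("num and den must have equal length")
  zero <- den == 0
  out <- num / den
  out[zero & num == 0] <- 0
  out[zero & num != 0] <- NA_real_
  attr(out, "mask") <- zero
  out
}
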