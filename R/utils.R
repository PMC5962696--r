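#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported ratio and quotient
#' scores so that printed values are reproducible independently of the IEEE
#' banker's rounding of [base::round()].
#'
#' @param x Numeric vector (non-negative in all pipeline uses).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small relative nudge so values computed as .x5 minus one ulp still round up
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Linear-interpolation percentile
#'
#' The percentile convention used throughout (quantile type 7: linear
#' interpolation between order statistics, the R default).
#'
#' @param x Numeric vector.
#' @param p Probability in \[0, 1\].
#' @return The interpolated percentile value.
#' @export
percentile <- function(x, p) {
  stopifnot(length(x) >= 1, is.finite(p), p >= 0, p <= 1)
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Geometric mean
#'
#' Zeros are replaced by 1 before taking logs (the usual convention for
#' digital count data); when that substitution fires, the result carries an
#' attribute `zeros_replaced` with the count.
#'
#' @param x Non-negative numeric vector.
#' @return Geometric mean (length-1 numeric).
#' @export
geometric_mean <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)), all(x >= 0))
  nz <- sum(x == 0)
  x[x == 0] <- 1
  out <- exp(mean(log(x)))
  if (nz > 0) attr(out, "zeros_replaced") <- nz
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
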