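#' Fusion/fission rate parameters
#'
#' Bundles the tip-to-tip fusion coefficient `a1`, the tip-to-side fusion
#' coefficient `a2`, and the fission coefficient `b`.  A single fission
#' machinery acts with equal probability per edge, so the per-node fission
#' rates are `b1 = b` for bulk nodes and `b2 = (3/2) b` for branching points
#' (three incident edges instead of two).  The steady state depends only on
#' the dimensionless ratios `c1 = a1/b` and `c2 = a2/b`.
#'
#' @param a1,a2 fusion propensity coefficients (per unit time), `>= 0`.
#' @param b fission coefficient (per unit time), `> 0` unless both fusions
#'   are also zero.
#' @param c1,c2 alternatively, the dimensionless ratios; used with `b`
#'   (default `b = 1`, dimensionless time) when `a1`/`a2` are missing.
#' @return object of class `rate_parameters` with fields `a1`, `a2`, `b`,
#'   `b1`, `b2`, `c1`, `c2`.
#' @examples
#' rate_parameters(c1 = 0.1, c2 = 1.9e-5)
#' @export
rate_parameters <- function(a1 = NULL, a2 = NULL, b = 1, c1 = NULL, c2 = NULL) {
  if (is.null(a1)) a1 <- if (is.null(c1)) stop("supply a1 or c1") else c1 * b
  if (is.null(a2)) a2 <- if (is.null(c2)) stop("supply a2 or c2") else c2 * b
  if (any(c(a1, a2, b) < 0)) stop("rates must be non-negative")
  structure(list(a1 = a1, a2 = a2, b = b, b1 = b, b2 = 1.5 * b,
                 c1 = if (b > 0) a1 / b else NA_real_,
                 c2 = if (b > 0) a2 / b else NA_real_),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat(sprintf(
    "<rate_parameters> a1 = %g, a2 = %g, b = %g (b2 = %g); c1 = %g, c2 = %g\n",
    x$a1, x$a2, x$b, x$b2, x$c1, x$c2))
  invisible(x)
}

#' Calibrate the fission coefficient to a physical event frequency
#'
#' Living-cell recordings put the summed frequency of fusion and fission
#' events at roughly 0.25 per cell per second.  At fixed ratios `(c1, c2)`
#' all propensities scale linearly in `b`, so matching the target total
#' event rate at the mean-field steady state fixes `b` (and hence physical
#' time units) uniquely.
#'
#' @param c1,c2 dimensionless rate ratios.
#' @param L edge count.
#' @param target_rate total stationary event frequency in 1/s
#'   (default 0.25).
#' @return a [rate_parameters()] object with `b` in 1/s.
#' @export
calibrate_rates <- function(c1, c2, L, target_rate = 0.25) {
  ss <- steady_state(c1, c2, L)
  per_b <- c1 * ss$x1 * (ss$x1 - 1) + ss$x2 + c2 * ss$x1 * ss$x2 + 1.5 * ss$x3
  if (per_b <= 0) stop("no events possible at this steady state")
  b <- target_rate / per_b
  rate_parameters(a1 = c1 * b, a2 = c2 * b, b = b)
}
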