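#' Mean-field node kinetics
#'
#' Right-hand side of the deterministic node-count equations.  Each of the
#' four elementary processes contributes its propensity times its census
#' increment:
#' \deqn{dx_1/dt = -2 a_1 x_1 (x_1 - 1) + 2 b x_2 - a_2 x_1 x_2 + (3/2) b x_3}
#' \deqn{dx_2/dt = \;\; a_1 x_1 (x_1 - 1) - b x_2 - a_2 x_1 x_2 + (3/2) b x_3}
#' \deqn{dx_3/dt = \;\; a_2 x_1 x_2 - (3/2) b x_3}
#' The discrete-pair form `x1 (x1 - 1)` is kept as printed (the number of
#' tip pairs times the per-pair propensity `2 a1`).  The combination
#' `dx1 + 2 dx2 + 3 dx3` vanishes identically, expressing conservation of
#' the edge count `L`.
#'
#' @param x numeric vector `(x1, x2, x3)` of non-negative reals.
#' @param rates a [rate_parameters()] object.
#' @return named numeric vector `(dx1, dx2, dx3)`.
#' @export
ode_rhs <- function(x, rates) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  f1 <- rates$a1 * x[1L] * (x[1L] - 1)  # tip-to-tip fusion propensity
  f2 <- rates$b * x[2L]                 # tip-to-tip fission
  f3 <- rates$a2 * x[1L] * x[2L]        # tip-to-side fusion
  f4 <- 1.5 * rates$b * x[3L]           # tip-to-side fission
  c(dx1 = -2 * f1 + 2 * f2 - f3 + f4,
    dx2 = f1 - f2 - f3 + f4,
    dx3 = f3 - f4)
}

#' Mean-field steady state
#'
#' The unique non-negative stationary point for given ratios `(c1, c2)` and
#' edge count `L`.  Setting the tip-to-side balance to zero gives
#' `x3 = (2/3) c2 x1 x2`; substituting into the tip balance gives
#' `x2 = c1 x1 (x1 - 1)`; `x1` is then the root of the conservation
#' constraint
#' `x1 + 2 c1 x1 (x1 - 1) (1 + c2 x1) = 2 L`,
#' bracketed on `(0, 2L]` and solved by bisection-safeguarded root finding
#' to relative tolerance 1e-12.
#'
#' @param c1 tip-to-tip fusion/fission ratio `a1/b`, `>= 0`.
#' @param c2 tip-to-side fusion/fission ratio `a2/b`, `>= 0`.
#' @param L edge count, `>= 1`.
#' @return object of class `steady_state`: list with `x1`, `x2`, `x3`,
#'   `c1`, `c2`, `L`, `n_segments = (x1 + 3 x3)/2` and
#'   `mean_segment_length`.
#' @examples
#' ss <- steady_state(0.1, 1.9e-5, 3e4)
#' ss$x1 / ss$x3   # ratio of tips to branching points
#' @export
steady_state <- function(c1, c2, L) {
  stopifnot(is.finite(c1), is.finite(c2), c1 >= 0, c2 >= 0, L >= 1)
  if (c1 == 0) {
    # no bulk nodes can form, hence no branching points either
    x1 <- 2 * L; x2 <- 0; x3 <- 0
  } else {
    f <- function(x1) x1 + 2 * c1 * x1 * (x1 - 1) * (1 + c2 * x1) - 2 * L
    fp <- function(x1) 1 + 2 * c1 * (2 * x1 - 1) + 2 * c1 * c2 * x1 * (3 * x1 - 2)
    lo <- min(1, 2 * L)
    if (f(lo) > 0) lo <- 0  # degenerate tiny-L guard
    root <- uniroot(f, c(lo, 2 * L), tol = 1e-12 * 2 * L)
    x1 <- root$root
    # Newton polish: the constraint can be extremely steep in x1, so the
    # bracketing tolerance alone leaves a visible conservation residual
    for (k in 1:6) {
      step <- f(x1) / fp(x1)
      if (!is.finite(step)) break
      x1 <- min(max(x1 - step, lo), 2 * L)
    }
    x2 <- c1 * x1 * (x1 - 1)
    x3 <- (2 * L - x1 - 2 * x2) / 3  # conservation, exact by construction
    if (min(x1, x2, x3) < -1e-9 * L)
      stop("steady-state solver produced a negative component")
    x3 <- max(x3, 0)
  }
  out <- list(x1 = x1, x2 = x2, x3 = x3, c1 = c1, c2 = c2, L = L,
              n_segments = (x1 + 3 * x3) / 2)
  out$mean_segment_length <- if (out$n_segments > 0) L / out$n_segments else NA_real_
  class(out) <- "steady_state"
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> c1 = %g, c2 = %g, L = %g\n  x = (%.6g, %.6g, %.6g); %.6g segments, mean length %.4g edges\n",
    x$c1, x$c2, x$L, x$x1, x$x2, x$x3, x$n_segments, x$mean_segment_length))
  invisible(x)
}

#' Mean non-loop segment length
#'
#' Every non-loop segment terminates in two slots held by degree-1 or
#' degree-3 nodes, so the segment count is `(x1 + 3 x3)/2` and the mean
#' length is `n = 2L / (x1 + 3 x3)` edges.  Loop mass (a few percent at
#' physiological parameters) is neglected, so the value is approximate as a
#' whole-network average.
#'
#' @param ss a [steady_state()] object.
#' @return mean segment length in edges (`>= 1`); errors in the single-loop
#'   regime `x1 + 3 x3 = 0` where no non-loop segment exists.
#' @export
mean_segment_length <- function(ss) {
  stopifnot(inherits(ss, "steady_state"))
  denom <- ss$x1 + 3 * ss$x3
  if (denom <= 0)
    stop("mean segment length undefined: no non-loop segments (single-loop regime)")
  2 * ss$L / denom
}

#' Steady-state surface over a parameter grid
#'
#' Evaluates [steady_state()] on the Cartesian grid `c1_grid x c2_grid`.
#'
#' @param c1_grid,c2_grid numeric vectors of non-negative ratios.
#' @param L edge count.
#' @return data frame with columns `c1`, `c2`, `x1`, `x2`, `x3`,
#'   `n_segments`, `mean_segment_length`.
#' @export
phase_surface <- function(c1_grid, c2_grid, L) {
  grid <- expand.grid(c1 = c1_grid, c2 = c2_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- steady_state(grid$c1[i], grid$c2[i], L)
    data.frame(c1 = ss$c1, c2 = ss$c2, x1 = ss$x1, x2 = ss$x2, x3 = ss$x3,
               n_segments = ss$n_segments,
               mean_segment_length = ss$mean_segment_length)
  })
  do.call(rbind, rows)
}
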