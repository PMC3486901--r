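#' Populations of open segments and loops (tip-to-tip-only network)
#'
#' With tip-to-side events switched off (`c2 = 0`) the network holds only
#' degree-1 and degree-2 nodes, i.e. open (1-1) segments and disconnected
#' (2-2) loops.  A `chain_populations` object stores the expected number
#' `u_open[i]` of open segments and `u_loop[i]` of loops of length `i`
#' edges, `i = 1..L` (the finite system truncates the support exactly at
#' `L`; a loop of a single edge is representable and allowed).
#'
#' @param u_open,u_loop non-negative numeric vectors of equal length `L`.
#' @return object of class `chain_populations` with fields `u_open`,
#'   `u_loop`, `L`, `N_open` (total open-segment count).
#' @export
chain_populations <- function(u_open, u_loop = numeric(length(u_open))) {
  stopifnot(length(u_open) == length(u_loop),
            all(u_open >= 0), all(u_loop >= 0))
  structure(list(u_open = as.numeric(u_open), u_loop = as.numeric(u_loop),
                 L = length(u_open), N_open = sum(u_open)),
            class = "chain_populations")
}

#' @export
print.chain_populations <- function(x, ...) {
  cat(sprintf(
    "<chain_populations> L = %d; %.4g open segments (mass %.4g), %.4g loops (mass %.4g)\n",
    x$L, sum(x$u_open), sum(seq_len(x$L) * x$u_open),
    sum(x$u_loop), sum(seq_len(x$L) * x$u_loop)))
  invisible(x)
}

#' Master equations for segment-length populations at c2 = 0
#'
#' Time derivative of the expected per-length populations under tip-to-tip
#' fusion and fission.  Rates follow the pair-propensity convention of the
#' node kinetics: every bulk node fissions at rate `b`; every unordered pair
#' of tips fuses at rate `2 a1`, so two distinct open segments (2 tips each,
#' 4 tip pairs) merge at rate `8 a1` and a segment closes into a loop (its
#' own 2 tips, one pair) at rate `2 a1`.  For `u_open[i]` the terms are:
#' creation by fission of longer segments, disruption by fission of its own
#' `i - 1` bulk nodes, creation by fission of same-size loops (`i` bulk
#' nodes each), formation by fusion of shorter segments, disruption by
#' fusion with different-size and with same-size segments, and loop
#' formation.  Loops obey `d u_loop[i]/dt = 2 a1 u_open[i] - i b u_loop[i]`.
#' Products of populations use the mass-action closure
#' (`u_open[j] * u_open[k]`), the standard Smoluchowski form; fusions that
#' would exceed the system size `L` are excluded from both gain and loss,
#' so edge mass `sum(i * (u_open + u_loop))` is conserved exactly and
#' populations stay non-negative.
#'
#' @param pop a [chain_populations()] object.
#' @param rates a [rate_parameters()] object (`a2` is ignored; the
#'   simplified network has no tip-to-side events).
#' @return list with numeric vectors `du_open`, `du_loop`.
#' @export
master_rhs <- function(pop, rates) {
  stopifnot(inherits(pop, "chain_populations"))
  u <- pop$u_open
  v <- pop$u_loop
  L <- pop$L
  i <- seq_len(L)
  a1 <- rates$a1
  b <- rates$b

  # (1) gain from fission of longer open segments: 2 per longer segment
  above <- rev(cumsum(rev(u)))                    # sum_{m >= i} u_m
  gain_fiss <- 2 * b * c(above[-1L], 0)           # sum over m > i
  # (2) loss from fission of own bulk nodes
  loss_fiss <- b * (i - 1) * u
  # (3) gain from fission of same-size loops
  gain_loop_fiss <- b * i * v
  # (4) gain from fusion of shorter segments
  conv <- pair_convolve_cpp(u)                    # sum_{j=1}^{i-1} u_j u_{i-j}
  gain_fus <- 4 * a1 * conv
  # (5, 6) loss from fusion with different-size / same-size partners,
  # restricted to partners that keep the product within the system size
  below <- cumsum(u)                              # sum_{j <= i} u_j
  partners <- ifelse(L - i >= 1, below[pmax(L - i, 1L)], 0)
  loss_fus <- 8 * a1 * u * partners
  # (7) loop formation
  loss_loop_form <- 2 * a1 * u

  du <- gain_fiss - loss_fiss + gain_loop_fiss + gain_fus - loss_fus -
    loss_loop_form
  dv <- 2 * a1 * u - b * i * v
  list(du_open = du, du_loop = dv)
}

#' Stationary segment-length distributions at c2 = 0
#'
#' Solves the master equations for their fixed point.  At stationarity the
#' loop populations satisfy `u_loop[i] = 2 c1 u_open[i] / i` exactly (loop
#' formation balances loop fission), which eliminates the loop terms from
#' the open-segment balance; the remaining system is solved by damped
#' fixed-point iteration (gain over loss rate, under-relaxed, with the
#' total edge mass projected back to `L` each sweep).  Convergence is
#' certified against the full [master_rhs()]: the returned populations
#' satisfy `max |rhs| <= tol * max(population)`.  The open-segment lengths
#' come out geometric up to the finite-size correction while loops carry
#' the extra `1/i` factor, so loops dominate among short segments and open
#' segments among long ones.
#'
#' @param c1 tip-to-tip fusion/fission ratio, `> 0`.
#' @param L edge count.
#' @param tol stationarity tolerance (default `1e-8`).
#' @param omega damping factor in (0, 1].
#' @param max_iter iteration budget.
#' @return a [chain_populations()] object with attribute `residual`.
#' @export
stationary_chain_populations <- function(c1, L, tol = 1e-8, omega = 0.3,
                                         max_iter = 50000L) {
  stopifnot(c1 > 0, L >= 2)
  a1 <- c1  # dimensionless time, b = 1
  rates <- rate_parameters(c1 = c1, c2 = 0)
  i <- seq_len(L)
  u <- c(L, numeric(L - 1L))  # fully fragmented start
  for (it in seq_len(max_iter)) {
    below <- cumsum(u)
    partners <- ifelse(L - i >= 1, below[pmax(L - i, 1L)], 0)
    loss_rate <- (i - 1) + 8 * a1 * partners  # fission + fusion, loops cancel
    above <- rev(cumsum(rev(u)))
    gain <- 2 * c(above[-1L], 0) + 4 * a1 * pair_convolve_cpp(u)
    u_new <- ifelse(loss_rate > 0, gain / loss_rate, u)
    u_new <- (1 - omega) * u + omega * u_new
    u_new <- u_new * L / (sum(i * u_new) + 2 * a1 * sum(u_new))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < 1e-14 * max(u)) break
  }
  pop <- chain_populations(u, 2 * a1 * u / i)
  r <- master_rhs(pop, rates)
  res <- max(abs(c(r$du_open, r$du_loop)))
  if (res > tol * max(u))
    stop(sprintf(
      "stationary solve did not converge: residual %.3g exceeds %.3g * max population",
      res, tol * max(u)))
  attr(pop, "residual") <- res
  pop
}
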