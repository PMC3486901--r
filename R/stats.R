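#' Segment census of a network state
#'
#' A segment is a maximal run of edges connected only through bulk
#' (degree-2) nodes.  Segments are typed by the degrees of their two end
#' nodes: `"1-1"` separate open-end segments, `"2-2"` disconnected loops,
#' `"1-3"` surface and `"3-3"` internal segments of branched clusters.
#' Implementation: two edges sharing a bulk node belong to the same segment,
#' so segments are the connected components of the edge graph linked through
#' bulk nodes (computed with igraph).
#'
#' @param state a [network_state()].
#' @return object of class `segment_census`: data frame with one row per
#'   segment, columns `segment`, `length` (edges), `type`, and (for cluster
#'   bookkeeping) `first_edge`; attribute `L`.
#' @examples
#' s <- network_state(5, "chain")
#' segment_census(s)
#' @export
segment_census <- function(state) {
  stopifnot(inherits(state, "network_state"))
  L <- state$L
  deg_of <- tabulate(state$node, nbins = max(state$node))
  slot_edge <- rep(seq_len(L), each = 2L)
  # link edges that share a bulk node
  bulk <- which(deg_of == 2L)
  el <- NULL
  if (length(bulk) > 0L) {
    slots_by_node <- split(seq_along(state$node), state$node)
    pairs <- slots_by_node[as.character(bulk)]
    el <- t(vapply(pairs, function(s) slot_edge[s], integer(2L)))
  }
  g <- igraph::make_empty_graph(n = L, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  memb <- igraph::components(g)$membership
  lengths <- as.integer(table(memb))
  # end degrees: slots of the segment held by non-bulk nodes
  slot_seg <- memb[slot_edge]
  end_slot <- deg_of[state$node] != 2L
  type <- vapply(seq_along(lengths), function(si) {
    ends <- sort(deg_of[state$node[end_slot & slot_seg == si]])
    if (length(ends) == 0L) return("2-2")
    paste(ends, collapse = "-")
  }, character(1L))
  first_edge <- vapply(seq_along(lengths), function(si)
    which(memb == si)[1L], integer(1L))
  out <- data.frame(segment = seq_along(lengths), length = lengths,
                    type = type, first_edge = first_edge)
  attr(out, "L") <- L
  class(out) <- c("segment_census", "data.frame")
  out
}

#' Cluster census of a network state
#'
#' Clusters are the connected components of the network.  Each is
#' characterized by its total edge count `j` and its segment count `r`.
#'
#' @param state a [network_state()].
#' @return object of class `cluster_census`: list with `clusters` (data
#'   frame of `j`, `r`), `g` (table of the number of r-segment clusters),
#'   `largest_fraction` (`max(j)/L`), and `susceptibility` (mean `r` over
#'   all clusters except the single largest; `NA` if only one cluster).
#' @export
cluster_census <- function(state) {
  stopifnot(inherits(state, "network_state"))
  L <- state$L
  segs <- segment_census(state)
  g <- as_igraph(state)
  memb <- igraph::components(g)$membership
  edge_cluster <- memb[igraph::ends(g, igraph::E(g), names = FALSE)[, 1L]]
  edge_cluster <- edge_cluster[order(igraph::E(g)$edge_id)]
  j <- as.integer(table(edge_cluster))
  r <- as.integer(table(factor(edge_cluster[segs$first_edge],
                               levels = seq_along(j))))
  imax <- which.max(j)
  susceptibility <- if (length(j) > 1L) mean(r[-imax]) else NA_real_
  gr <- table(r)
  structure(list(clusters = data.frame(cluster = seq_along(j), j = j, r = r),
                 g = gr, largest_fraction = max(j) / L,
                 susceptibility = susceptibility, L = L),
            class = "cluster_census")
}

#' @export
print.cluster_census <- function(x, ...) {
  cat(sprintf(
    "<cluster_census> %d clusters over %d edges; largest fraction %.3f; susceptibility %.3g\n",
    nrow(x$clusters), x$L, x$largest_fraction, x$susceptibility))
  invisible(x)
}

#' Fit a geometric law to segment lengths
#'
#' Segment lengths (in edges, support `1, 2, ...`) follow a geometric
#' distribution `p (1 - p)^(i - 1)` where `p` is the probability of a
#' segment end.  The maximum-likelihood estimate is `p = 1 / mean(length)`.
#' A chi-square goodness-of-fit statistic is computed over the bulk support
#' (cells pooled from the right so every expected count is at least 5),
#' with one degree of freedom deducted for the estimated `p`.
#'
#' @param lengths integer vector of observed segment lengths, or a named
#'   table/histogram of counts by length.
#' @return object of class `geometric_fit`: list with `p`, `mean_length`,
#'   `n`, `statistic`, `df`, `p_value`.
#' @export
fit_geometric <- function(lengths) {
  counts <- as_length_counts(lengths)
  n <- sum(counts$n)
  if (n == 0L) stop("empty length sample")
  mean_len <- sum(counts$i * counts$n) / n
  p <- 1 / mean_len
  gof <- if (n >= 10 && p < 1) {
    imax <- max(counts$i)
    obs <- numeric(imax)
    obs[counts$i] <- counts$n
    expd <- n * p * (1 - p)^(seq_len(imax) - 1)
    expd[imax] <- n * (1 - p)^(imax - 1)  # closed right tail
    chisq_pooled(obs, expd, n_estimated = 1L)
  } else {
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  structure(list(p = p, mean_length = mean_len, n = n,
                 statistic = gof$statistic, df = gof$df,
                 p_value = gof$p_value),
            class = "geometric_fit")
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf(
    "<geometric_fit> p = %.4g (mean length %.4g edges, n = %d); chi-square %.3g on %s df, p = %.3g\n",
    x$p, x$mean_length, x$n, x$statistic, format(x$df), x$p_value))
  invisible(x)
}

as_length_counts <- function(lengths) {
  if (is.table(lengths) || (!is.null(names(lengths)) && length(names(lengths)))) {
    i <- as.integer(names(lengths))
    n <- as.numeric(lengths)
  } else {
    tab <- table(lengths)
    i <- as.integer(names(tab))
    n <- as.numeric(tab)
  }
  keep <- n > 0
  data.frame(i = i[keep], n = n[keep])
}

# pool cells from the right until each expected count is >= 5
chisq_pooled <- function(obs, expd, n_estimated = 0L) {
  stopifnot(length(obs) == length(expd))
  o <- numeric(0); e <- numeric(0)
  co <- 0; ce <- 0
  for (k in rev(seq_along(obs))) {
    co <- co + obs[k]; ce <- ce + expd[k]
    if (ce >= 5 || k == 1L) {
      o <- c(co, o); e <- c(ce, e)
      co <- 0; ce <- 0
    }
  }
  if (length(o) > 1L && e[1L] < 5) {  # merge a deficient leading cell
    o[2L] <- o[2L] + o[1L]; e[2L] <- e[2L] + e[1L]
    o <- o[-1L]; e <- e[-1L]
  }
  df <- length(o) - 1L - n_estimated
  if (df < 1L)
    return(list(statistic = NA_real_, df = df, p_value = NA_real_))
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Negative binomial law for r-segment cluster sizes
#'
#' The size `j` (total edges) of a cluster made of `r` independent
#' geometric(`p`) segments is the sum of `r` geometric lengths, i.e. a
#' negative binomial on `j >= r`:
#' `P(j) = choose(j - 1, r - 1) p^r (1 - p)^(j - r)`.
#' In the finite system the law is truncated at `j = L` and renormalized.
#'
#' @param j integer cluster sizes (edges); values `< r` give probability 0
#'   with a warning.
#' @param r segment count, `>= 1`.
#' @param p probability of a segment end, in (0, 1).
#' @param L truncation size (default `Inf`, no truncation).
#' @return numeric vector of probabilities.
#' @examples
#' negbin_pmf(1:5, r = 1, p = 0.3)  # reduces to the geometric law
#' @export
negbin_pmf <- function(j, r, p, L = Inf) {
  stopifnot(r >= 1, p > 0, p < 1)
  if (any(j < r)) warning("cluster size j below segment count r has probability 0")
  out <- ifelse(j >= r, dnbinom(j - r, size = r, prob = p), 0)
  if (is.finite(L)) {
    norm <- sum(dnbinom(seq(r, L) - r, size = r, prob = p))
    out <- ifelse(j <= L, out / norm, 0)
  }
  out
}

#' Integral cluster-size distribution as a mixture over segment counts
#'
#' `n(j) = sum_r g(r) * negbin_pmf(j, r, p)`: the expected number of
#' clusters of size `j`, weighting the per-`r` negative binomial laws by the
#' simulated number `g(r)` of r-segment clusters (no closed form is known
#' for `g`).
#'
#' @param census a [cluster_census()] (its `g` table supplies the weights),
#'   or a named numeric vector/table `g(r)`.
#' @param p probability of a segment end.
#' @param j_max largest size to tabulate (default `L` when available).
#' @return data frame with columns `j` and `n` (expected cluster counts).
#' @export
cluster_size_mixture <- function(census, p, j_max = NULL) {
  g <- if (inherits(census, "cluster_census")) census$g else census
  if (is.null(j_max))
    j_max <- if (inherits(census, "cluster_census")) census$L else 10 * max(as.integer(names(g))) / p
  r_vals <- as.integer(names(g))
  j <- seq_len(j_max)
  n <- numeric(j_max)
  for (k in seq_along(r_vals)) {
    n <- n + as.numeric(g[k]) *
      suppressWarnings(negbin_pmf(j, r_vals[k], p, L = j_max))
  }
  data.frame(j = j, n = n)
}

#' Cluster size versus segment count scatter
#'
#' Per-cluster `(r, j)` pairs with the least-squares slope of `j` on `r`
#' through the origin.  The slope estimates the mean segment length; the
#' residual spread grows near the percolation transition.
#'
#' @param census a [cluster_census()].
#' @return list with `pairs` (data frame `r`, `j`), `slope`, and
#'   `residual_sd`.
#' @export
scatter_j_vs_r <- function(census) {
  stopifnot(inherits(census, "cluster_census"))
  cl <- census$clusters
  slope <- sum(cl$j * cl$r) / sum(cl$r^2)
  resid <- cl$j - slope * cl$r
  list(pairs = cl[, c("r", "j")], slope = slope,
       residual_sd = if (nrow(cl) > 1L) sqrt(sum(resid^2) / (nrow(cl) - 1L)) else 0)
}

#' Percolation scan over the tip-to-side ratio
#'
#' For each `c2` on a (log-spaced) grid the network is simulated to
#' stationarity and the largest-cluster edge fraction and susceptibility
#' (mean segment count over non-giant clusters) are averaged over
#' decorrelated snapshots.  The critical ratio is estimated as the location
#' of the susceptibility peak, refined by a local quadratic fit of
#' susceptibility against `log(c2)` around the grid maximum.
#'
#' @param c1 tip-to-tip ratio held fixed.
#' @param L edge count.
#' @param c2_grid increasing vector of tip-to-side ratios (>= 12 log-spaced
#'   values spanning the transition recommended).
#' @param n_snapshots stationary snapshots per grid point (default 30).
#' @param burn_in events before sampling (default `10 * L`).
#' @param sample_every events between snapshots (default `L`).
#' @param seed integer seed, or `NULL`.
#' @param refine when `TRUE`, a second stage re-scans `refine_points`
#'   log-spaced values spanning a factor `refine_span` around the coarse
#'   peak with `4 * n_snapshots` snapshots each, and the peak is re-fit
#'   there; sharpens the critical estimate, since the susceptibility peak
#'   is asymmetric and flat-topped at finite `L`.
#' @param refine_points,refine_span refinement-stage grid settings.
#' @return object of class `percolation_scan`: list with `table` (per-c2
#'   means and standard errors), `c2_critical` (quadratic-fit peak; `NA`
#'   with `boundary = TRUE` if the peak sits on the grid edge),
#'   `largest_fraction_critical` (largest fraction at the grid point nearest
#'   the peak), `refined_table` (when refined), and the scan settings.
#' @export
percolation_scan <- function(c1, L, c2_grid, n_snapshots = 30L,
                             burn_in = 10 * L, sample_every = L,
                             seed = NULL, refine = FALSE,
                             refine_points = 7L, refine_span = 4) {
  stopifnot(length(c2_grid) >= 3L, !is.unsorted(c2_grid))
  if (!is.null(seed)) set.seed(seed)
  tab <- scan_grid(c1, L, c2_grid, n_snapshots, burn_in, sample_every)
  peak <- peak_from_table(tab)
  refined_table <- NULL
  if (refine && !peak$boundary) {
    rg <- 10^seq(log10(peak$c2 / sqrt(refine_span)),
                 log10(peak$c2 * sqrt(refine_span)),
                 length.out = refine_points)
    refined_table <- scan_grid(c1, L, rg, 4L * n_snapshots, burn_in,
                               sample_every)
    rpeak <- peak_from_table(refined_table)
    if (!rpeak$boundary) peak <- rpeak
  }
  lf_tab <- if (!is.null(refined_table)) refined_table else tab
  lf_crit <- if (peak$boundary) NA_real_ else
    lf_tab$largest_fraction[which.min(abs(log(lf_tab$c2) - log(peak$c2)))]
  structure(list(table = tab, refined_table = refined_table,
                 c2_critical = peak$c2, boundary = peak$boundary,
                 largest_fraction_critical = lf_crit, c1 = c1, L = L,
                 n_snapshots = n_snapshots, seed = seed),
            class = "percolation_scan")
}

scan_grid <- function(c1, L, c2_grid, n_snapshots, burn_in, sample_every) {
  rows <- lapply(c2_grid, function(c2) {
    cfg <- simulation_config(rate_parameters(c1 = c1, c2 = c2), L = L,
                             seed = NULL, burn_in = burn_in,
                             max_events = n_snapshots * sample_every,
                             sample_every = sample_every)
    traj <- simulate_network(cfg, record = "stats")
    s <- traj$samples
    data.frame(
      c2 = c2,
      largest_fraction = mean(s$largest_fraction),
      largest_fraction_se = sd_err(s$largest_fraction),
      susceptibility = mean(s$susceptibility, na.rm = TRUE),
      susceptibility_se = sd_err(s$susceptibility[!is.na(s$susceptibility)]),
      x1 = mean(s$x1), x2 = mean(s$x2), x3 = mean(s$x3),
      n_snapshots = nrow(s))
  })
  do.call(rbind, rows)
}

# local quadratic fit of susceptibility against log(c2) around the maximum
peak_from_table <- function(tab) {
  k <- which.max(tab$susceptibility)
  if (k == 1L || k == nrow(tab))
    return(list(c2 = NA_real_, boundary = TRUE))
  idx <- (k - 1L):(k + 1L)
  fit <- lm(y ~ x + I(x^2),
            data = data.frame(x = log(tab$c2[idx]), y = tab$susceptibility[idx]))
  co <- coef(fit)
  peak <- if (is.finite(co[3L]) && co[3L] < 0) -co[2L] / (2 * co[3L]) else
    log(tab$c2[k])
  peak <- min(max(peak, log(tab$c2[k - 1L])), log(tab$c2[k + 1L]))
  list(c2 = exp(peak), boundary = FALSE)
}

#' @export
print.percolation_scan <- function(x, ...) {
  cat(sprintf(
    "<percolation_scan> c1 = %g, L = %g, %d grid points; c2_critical = %.3g; largest fraction there = %.3f\n",
    x$c1, x$L, nrow(x$table), x$c2_critical, x$largest_fraction_critical))
  invisible(x)
}

sd_err <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_

#' Pooled segment lengths from stationary snapshots
#'
#' Convenience sampler: simulates to stationarity and pools the segment
#' census (and, optionally, the cluster census) over decorrelated
#' snapshots taken from the compiled simulator.
#'
#' @param c1,c2 rate ratios.
#' @param L edge count.
#' @param n_snapshots snapshots to pool.
#' @param burn_in,sample_every event counts (defaults `10 * L` and `L`).
#' @param seed integer seed, or `NULL`.
#' @return list with data frames `segments` (`length`, `type`) and
#'   `clusters` (`j`, `r`), pooled over snapshots.
#' @export
sample_structure <- function(c1, c2, L, n_snapshots = 20L, burn_in = 10 * L,
                             sample_every = L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- rate_parameters(c1 = c1, c2 = c2)
  ptr <- ns_new_cpp(as.integer(L), "fragmented")
  ns_advance_cpp(ptr, r$a1, r$a2, r$b, burn_in)
  seg <- vector("list", n_snapshots)
  clu <- vector("list", n_snapshots)
  for (k in seq_len(n_snapshots)) {
    ns_advance_cpp(ptr, r$a1, r$a2, r$b, sample_every)
    sc <- ns_segment_census_cpp(ptr)
    seg[[k]] <- data.frame(length = sc$length,
                           type = type_label(sc$type), snapshot = k)
    cs <- ns_cluster_stats_cpp(ptr)
    clu[[k]] <- data.frame(j = cs$j, r = cs$r, snapshot = k)
  }
  list(segments = do.call(rbind, seg), clusters = do.call(rbind, clu))
}

type_label <- function(code) {
  c(`11` = "1-1", `13` = "1-3", `22` = "2-2", `33` = "3-3")[as.character(code)]
}
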