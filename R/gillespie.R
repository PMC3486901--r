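#' Event propensities at a node census
#'
#' Total propensities of the four elementary events at census
#' `x = (x1, x2, x3)`: tip-to-tip fusion `a1 x1 (x1 - 1)` (the number of tip
#' pairs `x1 (x1 - 1) / 2` times the per-pair propensity `2 a1`), tip-to-tip
#' fission `b x2`, tip-to-side fusion `a2 x1 x2`, and tip-to-side fission
#' `(3/2) b x3`.
#'
#' @param census numeric vector `(x1, x2, x3)` of non-negative node counts.
#' @param rates a [rate_parameters()] object.
#' @return named numeric vector of the four propensities.
#' @export
propensities <- function(census, rates) {
  x <- as.numeric(census)
  if (length(x) != 3L || any(x < 0)) stop("census must be 3 non-negative counts")
  c(fuse_tip_tip = rates$a1 * x[1L] * (x[1L] - 1),
    fiss_tip_tip = rates$b * x[2L],
    fuse_tip_side = rates$a2 * x[1L] * x[2L],
    fiss_tip_side = 1.5 * rates$b * x[3L])
}

#' Configuration for a stochastic simulation run
#'
#' @param rates a [rate_parameters()] object.
#' @param L edge count.
#' @param seed integer RNG seed, or `NULL` to leave the RNG stream alone.
#' @param max_events events to execute after burn-in.
#' @param burn_in events discarded before recording starts.
#' @param sample_every recording cadence in events.
#' @param initial_state `"fragmented"`, `"chain"` or `"loop"`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(rates, L, seed = NULL, max_events = 10 * L,
                              burn_in = 10 * L, sample_every = L,
                              initial_state = c("fragmented", "chain", "loop")) {
  stopifnot(inherits(rates, "rate_parameters"), L >= 1, sample_every >= 1,
            max_events >= 1, burn_in >= 0)
  structure(list(rates = rates, L = as.integer(L), seed = seed,
                 max_events = max_events, burn_in = burn_in,
                 sample_every = sample_every,
                 initial_state = match.arg(initial_state)),
            class = "simulation_config")
}

#' Exact stochastic simulation of the reticulum dynamics
#'
#' Runs the Gillespie algorithm on the dynamic graph: waiting times are
#' exponential with rate equal to the summed propensity, the event type is
#' drawn categorically by propensity, and participants are drawn uniformly
#' among nodes of the eligible degree (for tip-to-tip fusion, uniformly
#' among unordered distinct tip pairs; for tip-to-side fission, uniformly
#' among the three incident edges).  The compiled core executes each event
#' in O(1) amortized time.
#'
#' @param config a [simulation_config()].
#' @param record `"census"` records `(time, x1, x2, x3)` at each sample;
#'   `"stats"` additionally records the largest-cluster edge fraction and
#'   the susceptibility (mean segment count over non-giant clusters).
#' @return object of class `trajectory`: a list with `samples` (data frame),
#'   `config`, `final_state` (a [network_state()]), `event_counts`, and
#'   `absorbed` (`TRUE` if an absorbing census was reached before the
#'   stopping rule, in which case the trajectory is truncated).
#' @examples
#' cfg <- simulation_config(rate_parameters(c1 = 1, c2 = 0.01), L = 50,
#'                          seed = 1, max_events = 2000, burn_in = 500,
#'                          sample_every = 100)
#' traj <- simulate_network(cfg)
#' head(traj$samples)
#' @export
simulate_network <- function(config, record = c("census", "stats")) {
  stopifnot(inherits(config, "simulation_config"))
  record <- match.arg(record)
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- config$rates
  ptr <- ns_new_cpp(config$L, config$initial_state)
  event_counts <- c(fuse_tip_tip = 0, fiss_tip_tip = 0,
                    fuse_tip_side = 0, fiss_tip_side = 0)
  absorbed <- FALSE
  if (config$burn_in > 0) {
    adv <- ns_advance_cpp(ptr, r$a1, r$a2, r$b, config$burn_in)
    event_counts <- event_counts + adv$event_counts
    absorbed <- adv$absorbed
  }
  n_samples <- floor(config$max_events / config$sample_every)
  rows <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    if (absorbed) break
    adv <- ns_advance_cpp(ptr, r$a1, r$a2, r$b, config$sample_every)
    event_counts <- event_counts + adv$event_counts
    absorbed <- adv$absorbed
    if (absorbed && adv$events < config$sample_every) break
    cen <- ns_census_cpp(ptr)
    row <- data.frame(time = ns_time_cpp(ptr), x1 = cen[1L], x2 = cen[2L],
                      x3 = cen[3L])
    if (record == "stats") {
      cs <- ns_cluster_stats_cpp(ptr)
      row$largest_fraction <- cs$largest_fraction
      row$susceptibility <- cs$susceptibility
      row$n_clusters <- length(cs$j)
    }
    rows[[k]] <- row
  }
  samples <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  structure(list(samples = samples, config = config,
                 final_state = snapshot_state(ptr),
                 event_counts = event_counts, absorbed = absorbed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- if (is.null(x$samples)) 0L else nrow(x$samples)
  cat(sprintf("<trajectory> L = %d, %d samples, %g events%s\n",
              x$config$L, n, sum(x$event_counts),
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

snapshot_state <- function(ptr) {
  m <- ns_snapshot_cpp(ptr)
  new_network_state(nrow(m), as.integer(t(m)))
}

#' Single Gillespie step on an R-level network state
#'
#' Draws a waiting time and event per the Gillespie algorithm and applies
#' the event to `state`.  Intended for small-scale inspection and testing;
#' production runs go through [simulate_network()].
#'
#' @param state a [network_state()].
#' @param rates a [rate_parameters()] object.
#' @return list with `state`, `dt`, `event` (name or `NA`), and `absorbed`;
#'   when every propensity is zero the state is returned unchanged with
#'   `absorbed = TRUE` (absorbing-state signal, not an error).
#' @export
step_network <- function(state, rates) {
  a <- propensities(census(state), rates)
  tot <- sum(a)
  if (tot <= 0)
    return(list(state = state, dt = NA_real_, event = NA_character_,
                absorbed = TRUE))
  dt <- rexp(1L, tot)
  ev <- sample.int(4L, 1L, prob = a)
  state <- switch(ev,
    {
      tips <- sample(nodes_of_degree(state, 1L), 2L)
      fuse_tip_tip(state, tips[1L], tips[2L])
    },
    fiss_tip_tip(state, resample1(nodes_of_degree(state, 2L))),
    fuse_tip_side(state, resample1(nodes_of_degree(state, 1L)),
                  resample1(nodes_of_degree(state, 2L))),
    {
      br <- resample1(nodes_of_degree(state, 3L))
      edges <- (which(state$node == br) + 1L) %/% 2L
      fiss_tip_side(state, br, resample1(edges))
    })
  list(state = state, dt = dt, event = names(a)[ev], absorbed = FALSE)
}

# sample() treats a length-1 vector as 1:n; avoid that
resample1 <- function(x) x[sample.int(length(x), 1L)]
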