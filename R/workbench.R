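#' Edge count from physical length
#'
#' Discretizes a total mitochondrial length into network edges: the edge
#' length is set by the tubule diameter (about 0.2 micrometres, the size of
#' a maximally fragmented vesicle), so `L = round(total / edge_length)`.
#' For a HeLa-scale chondriome of 5000 um this gives `L = 3e4`.
#'
#' @param total_length_um total mitochondrial length, in micrometres.
#' @param edge_length_um edge (tubule diameter) length, in micrometres
#'   (default 0.2).
#' @return integer edge count `L`.
#' @examples
#' edges_from_length(5000, 0.2)
#' @export
edges_from_length <- function(total_length_um, edge_length_um = 0.2) {
  if (!is.numeric(total_length_um) || total_length_um <= 0 ||
      !is.numeric(edge_length_um) || edge_length_um <= 0)
    stop("lengths must be positive")
  as.integer(round(total_length_um / edge_length_um))
}

#' Percolation transition report
#'
#' End-to-end reproduction of the percolation analysis: runs
#' [percolation_scan()] at the given `c1` and `L`, and evaluates the
#' tip-to-branching-point ratio `x1/x3` at three reference `c2` values
#' (sub-, near- and supercritical) from both the mean-field steady state
#' and the stationary simulation.
#'
#' @param c1 tip-to-tip ratio (default 0.1).
#' @param L edge count (default 3e4).
#' @param c2_grid scan grid (default 16 log-spaced points, 2e-6 to 2e-4).
#' @param c2_reference `c2` values at which `x1/x3` is reported.
#' @param n_snapshots snapshots per scan point.
#' @param seed integer seed.
#' @param out optional output directory; when given, writes `scan.csv`,
#'   `report.json` and returns paths in the report.
#' @return list with `scan` (a [percolation_scan()]), `c2_critical`,
#'   `largest_fraction_critical`, `ratios` (data frame of mean-field and
#'   simulated `x1/x3`), `seed`, and `version`.
#' @export
percolation_report <- function(c1 = 0.1, L = 3e4,
                               c2_grid = 10^seq(log10(2e-6), log10(2e-4),
                                                length.out = 16),
                               c2_reference = c(1.7e-6, 1.9e-5, 5.0e-4),
                               n_snapshots = 30L, seed = 1L, out = NULL) {
  set.seed(seed)
  scan <- percolation_scan(c1, L, c2_grid, n_snapshots = n_snapshots,
                           seed = NULL)
  ratios <- do.call(rbind, lapply(c2_reference, function(c2) {
    ss <- steady_state(c1, c2, L)
    cfg <- simulation_config(rate_parameters(c1 = c1, c2 = c2), L = L,
                             burn_in = 10 * L, max_events = 30L * L,
                             sample_every = L)
    traj <- simulate_network(cfg)
    data.frame(c2 = c2, ratio_meanfield = ss$x1 / ss$x3,
               ratio_simulated = mean(traj$samples$x1) / mean(traj$samples$x3))
  }))
  report <- list(scan = scan, c2_critical = scan$c2_critical,
                 largest_fraction_critical = scan$largest_fraction_critical,
                 ratios = ratios, seed = seed, c1 = c1, L = L,
                 version = package_version_string())
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.csv(scan$table, file.path(out, "scan.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(c1 = c1, L = L, seed = seed, version = report$version,
           c2_critical = scan$c2_critical,
           largest_fraction_critical = scan$largest_fraction_critical,
           ratios = ratios),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    report$files <- file.path(out, c("scan.csv", "report.json"))
  }
  stopifnot(validate_report_schema(report))
  report
}

#' Segment and cluster statistics report
#'
#' Reproduces the structural-distribution analysis: pooled segment-length
#' histograms by type with geometric fits at each `(c1, c2)` pair, and, at
#' the near-critical parameter set, negative binomial fits of the cluster
#' sizes for fixed segment counts plus the size-versus-segment-count
#' scatter slope.
#'
#' @param parameter_pairs data frame with columns `c1`, `c2` (default: the
#'   four combinations of `c1` in {0.1, 10} and `c2` in {5e-5, 5e-6}).
#' @param cluster_set list with `c1`, `c2` for the cluster-size analysis
#'   (default `c1 = 0.1`, `c2 = 2.2e-5`, near the transition).
#' @param r_values segment counts for the per-`r` negative binomial fits.
#' @param L edge count.
#' @param n_snapshots pooled snapshots per parameter set.
#' @param seed integer seed.
#' @return list with `segment_fits` (per parameter pair: mean lengths by
#'   type and [fit_geometric()] of the pooled non-loop lengths),
#'   `cluster_fits` (per `r`: sample size and chi-square of the negative
#'   binomial law), `scatter_slope`, `mixture` (integral size
#'   distribution), `seed`, `version`.
#' @export
segment_cluster_report <- function(parameter_pairs = expand.grid(
                                     c1 = c(0.1, 10), c2 = c(5e-5, 5e-6)),
                                   cluster_set = list(c1 = 0.1, c2 = 2.2e-5),
                                   r_values = c(1L, 3L, 5L), L = 3e4,
                                   n_snapshots = 20L, seed = 1L) {
  set.seed(seed)
  segment_fits <- lapply(seq_len(nrow(parameter_pairs)), function(k) {
    c1 <- parameter_pairs$c1[k]; c2 <- parameter_pairs$c2[k]
    str <- sample_structure(c1, c2, L, n_snapshots = n_snapshots)
    nonloop <- str$segments[str$segments$type != "2-2", ]
    list(c1 = c1, c2 = c2,
         mean_length_by_type = tapply(str$segments$length,
                                      str$segments$type, mean),
         geometric_fit = fit_geometric(nonloop$length),
         loop_mass_fraction = sum(str$segments$length[
           str$segments$type == "2-2"]) / (n_snapshots * L))
  })
  str <- sample_structure(cluster_set$c1, cluster_set$c2, L,
                          n_snapshots = n_snapshots)
  nonloop <- str$segments[str$segments$type != "2-2", ]
  p_hat <- fit_geometric(nonloop$length)$p
  cluster_fits <- lapply(r_values, function(r) {
    sizes <- str$clusters$j[str$clusters$r == r]
    gof <- negbin_gof(sizes, r, p_hat)
    list(r = r, n = length(sizes), p = p_hat,
         statistic = gof$statistic, df = gof$df, p_value = gof$p_value)
  })
  g <- table(str$clusters$r) / n_snapshots
  slope <- sum(str$clusters$j * str$clusters$r) / sum(str$clusters$r^2)
  list(segment_fits = segment_fits, cluster_fits = cluster_fits,
       scatter_slope = slope,
       mixture = cluster_size_mixture(g, p_hat, j_max = L),
       p = p_hat, seed = seed, version = package_version_string())
}

# chi-square adequacy of the negative binomial cluster-size law at fixed r
negbin_gof <- function(sizes, r, p) {
  if (length(sizes) < 20L)
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  jmax <- max(sizes)
  obs <- tabulate(sizes, nbins = jmax)[r:jmax]
  prob <- suppressWarnings(negbin_pmf(r:jmax, r, p))
  prob[length(prob)] <- prob[length(prob)] +
    max(0, 1 - sum(prob))  # close the right tail
  chisq_pooled(obs, length(sizes) * prob, n_estimated = 1L)
}

validate_report_schema <- function(report) {
  needed <- c("scan", "c2_critical", "largest_fraction_critical", "ratios",
              "seed", "version")
  all(needed %in% names(report)) &&
    inherits(report$scan, "percolation_scan") &&
    is.data.frame(report$ratios) &&
    all(c("c2", "ratio_meanfield", "ratio_simulated") %in%
          names(report$ratios))
}

package_version_string <- function() {
  paste0("mitoreticulum ",
         as.character(utils::packageVersion("mitoreticulum")))
}
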