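# 2-edge segment plus 1-edge segment fused into a "T"
t_network <- function() {
  s <- mitoreticulum:::new_network_state(
    3L, c(1L, 2L, 2L, 3L, 4L, 5L))  # chain of 2 + isolated edge
  fuse_tip_side(s, 4L, 2L)
}

disjoint_chains <- function(n1, n2) {
  a <- network_state(n1, "chain")
  b <- network_state(n2, "chain")
  mitoreticulum:::new_network_state(n1 + n2, c(a$node, b$node + max(a$node)))
}

cluster_r <- function(state) {
  cl <- cluster_census(state)
  expect_equal(nrow(cl$clusters), 1L)
  cl$clusters$r
}

test_that("segment census types and lengths match hand enumeration", {
  # 5-edge chain: one open segment of length 5
  segs <- segment_census(network_state(5, "chain"))
  expect_equal(segs$length, 5L)
  expect_equal(segs$type, "1-1")
  # loop of 4 edges: one 2-2 segment
  segs <- segment_census(network_state(4, "loop"))
  expect_equal(segs$type, "2-2")
  expect_equal(segs$length, 4L)
  # "T": three 1-3 segments of length 1
  segs <- segment_census(t_network())
  expect_equal(segs$length, rep(1L, 3))
  expect_equal(segs$type, rep("1-3", 3))
})

test_that("cluster census reports (j, r) pairs, largest fraction and susceptibility", {
  # two disjoint chains of 3 and 2 edges
  s <- disjoint_chains(3L, 2L)
  cl <- cluster_census(s)
  expect_setequal(paste(cl$clusters$j, cl$clusters$r), c("3 1", "2 1"))
  expect_equal(cl$largest_fraction, 0.6)
  expect_equal(cl$susceptibility, 1)
  # archetypal r = 1, 2, 3 cluster topologies: a chain, a cycle with a
  # tail (one tip + one branch point), and a "T"
  expect_equal(cluster_r(network_state(4, "chain")), 1L)
  lolli <- local({
    s <- network_state(4, "chain")
    fuse_tip_side(s, nodes_of_degree(s, 1L)[1L], nodes_of_degree(s, 2L)[2L])
  })
  expect_equal(cluster_r(lolli), 2L)
  expect_equal(cluster_r(t_network()), 3L)
})

test_that("censuses agree with independent traversal oracles on random states", {
  set.seed(99)
  for (rep in 1:30) {
    state <- random_state(sample(5:40, 1L))
    segs <- segment_census(state)
    want <- oracle_segments(state)
    got <- segs[order(segs$type, segs$length), c("length", "type")]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    expect_equal(sum(segs$length), state$L)  # edge-mass closure
    cl <- cluster_census(state)
    expect_equal(sort(cl$clusters$j), oracle_clusters(state))
    expect_equal(sum(cl$clusters$j), state$L)
  }
})

test_that("geometric fitting recovers the segment-end probability", {
  expect_equal(fit_geometric(rep(1L, 50))$p, 1)
  set.seed(123)
  sample_lengths <- rgeom(1e5, 0.2) + 1L
  fit <- fit_geometric(sample_lengths)
  expect_lt(abs(fit$p - 0.2), 0.005)
  expect_gt(fit$p_value, 0.01)
  expect_error(fit_geometric(integer(0)), "empty")
})

test_that("the negative binomial law reduces, normalizes and warns correctly", {
  p <- 0.3
  j <- 1:40
  expect_equal(negbin_pmf(j, 1, p), p * (1 - p)^(j - 1))
  for (r in c(1, 3, 5))
    expect_equal(sum(negbin_pmf(r:500, r, p, L = 500)), 1, tolerance = 1e-12)
  expect_warning(out <- negbin_pmf(2, 5, p), "probability 0")
  expect_equal(out, 0)
})

test_that("the cluster-size mixture collapses to a geometric law for r = 1 only", {
  g <- c(`1` = 80)
  mix <- cluster_size_mixture(g, p = 0.25, j_max = 200)
  expect_equal(mix$n, 80 * negbin_pmf(1:200, 1, 0.25, L = 200), tolerance = 1e-12)
})

test_that("scatter of cluster size against segment count estimates mean length", {
  uniform <- structure(list(
    clusters = data.frame(cluster = 1:6, j = rep(5L, 6), r = rep(1L, 6)),
    g = table(rep(1L, 6)), largest_fraction = NA, susceptibility = NA,
    L = 30), class = "cluster_census")
  sc <- scatter_j_vs_r(uniform)
  expect_equal(sc$slope, 5)
  expect_equal(sc$residual_sd, 0)
})

test_that("a scaled-down scan shows the percolation transition in c2", {
  # the critical ratio scales like 1/L, so a 3e3-edge system is scanned on
  # a ten-fold larger c2 window
  L <- 3000
  grid <- 10^seq(log10(2e-5), log10(2e-3), length.out = 12)
  scan <- percolation_scan(0.1, L, grid, n_snapshots = 20L, seed = 77)
  tab <- scan$table
  expect_lt(tab$largest_fraction[1], 0.15)       # subcritical start
  expect_gt(tab$largest_fraction[nrow(tab)], 0.6)  # supercritical end
  expect_false(scan$boundary)                    # interior susceptibility peak
  expect_gt(cor(log(tab$c2), tab$largest_fraction, method = "spearman"), 0.9)
  # the j-vs-r scatter slope tracks the mean non-loop segment length
  set.seed(78)
  str <- sample_structure(0.1, scan$c2_critical, L, n_snapshots = 20L)
  nonloop <- str$segments[str$segments$type != "2-2", ]
  slope <- sum(str$clusters$j * str$clusters$r) / sum(str$clusters$r^2)
  expect_lt(abs(slope - mean(nonloop$length)) / mean(nonloop$length), 0.05)
})
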