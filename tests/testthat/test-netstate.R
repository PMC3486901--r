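# the tip node ids of edge e in a fragmented state
state_tip <- function(state, e) state$node[2L * e - 1L]

# disjoint union of two states (relabels the second's nodes and edges)
merge_states <- function(a, b) {
  shift <- max(a$node)
  mitoreticulum:::new_network_state(a$L + b$L, c(a$node, b$node + shift))
}

test_that("elementary operations change the census by the reaction stoichiometry", {
  # two single-edge segments, fuse one tip of each
  s <- network_state(2, "fragmented")
  expect_equal(unname(census(s)), c(4L, 0L, 0L))
  s2 <- fuse_tip_tip(s, state_tip(s, 1L), state_tip(s, 2L))
  expect_equal(unname(census(s2)), c(2L, 1L, 0L))

  # closing the two tips of one 2-edge segment yields a loop
  chain <- network_state(2, "chain")
  expect_equal(unname(census(chain)), c(2L, 1L, 0L))
  tips <- nodes_of_degree(chain, 1L)
  loop <- fuse_tip_tip(chain, tips[1L], tips[2L])
  expect_equal(unname(census(loop)), c(0L, 2L, 0L))
  expect_equal(nrow(cluster_census(loop)$clusters), 1L)

  # 1-edge loop fission gives back a single open edge
  tiny <- network_state(1, "loop")
  expect_equal(unname(census(tiny)), c(0L, 1L, 0L))
  expect_equal(unname(census(fiss_tip_tip(tiny, tiny$node[1L]))), c(2L, 0L, 0L))

  # "T" from a 2-edge segment plus a 1-edge segment
  s <- merge_states(network_state(2, "chain"), network_state(1, "chain"))
  expect_equal(unname(census(s)), c(4L, 1L, 0L))
  t_state <- fuse_tip_side(s, nodes_of_degree(s, 1L)[1L], nodes_of_degree(s, 2L)[1L])
  expect_equal(unname(census(t_state)), c(3L, 0L, 1L))

  # tip-side fission reverses the census for any edge choice
  br <- nodes_of_degree(t_state, 3L)
  for (e in (which(t_state$node == br) + 1L) %/% 2L)
    expect_equal(unname(census(fiss_tip_side(t_state, br, e))), c(4L, 1L, 0L))
})

test_that("operations reject invalid operands", {
  chain <- network_state(3, "chain")
  tip <- nodes_of_degree(chain, 1L)[1L]
  bulk <- nodes_of_degree(chain, 2L)[1L]
  expect_error(fuse_tip_tip(chain, tip, tip), "distinct")
  expect_error(fuse_tip_tip(chain, tip, bulk), "degree 1")
  expect_error(fiss_tip_tip(chain, tip), "degree 2")
  expect_error(fuse_tip_side(chain, bulk, tip), "degree")
  expect_error(fiss_tip_side(chain, bulk, 1L), "degree 3")
})

test_that("splitting the middle of a 3-edge chain gives segments of 1 and 2 edges", {
  chain <- network_state(3, "chain")
  mid <- nodes_of_degree(chain, 2L)  # two bulk nodes; split each in turn
  for (b in mid) {
    parts <- segment_census(fiss_tip_tip(chain, b))
    expect_setequal(parts$length, c(1L, 2L))
    expect_true(all(parts$type == "1-1"))
  }
})

test_that("incremental and from-scratch censuses agree over random operation walks", {
  set.seed(421)
  for (rep in 1:60) {
    L <- sample(3:50, 1L)
    state <- network_state(L, sample(c("fragmented", "chain", "loop"), 1L))
    cen <- census(state)
    for (k in 1:40) {
      step <- random_valid_op(state)
      if (is.null(step)) break
      state <- step$state
      cen <- cen + step$delta
      expect_identical(unname(census(state)), unname(cen))
      # conservation and degree bounds at every step
      expect_identical(sum(cen * c(1L, 2L, 3L)), 2L * L)
      expect_true(all(table(state$node) %in% 1:3))
    }
    validate_network_state(state)
  }
})

test_that("exhaustive tip-to-tip fusion cascades from isolated edges end in loops only", {
  # enumerate every fusion sequence for small L: conservation holds
  # throughout and each terminal state has no tips left (x1 is even, each
  # fusion removes 2), i.e. x = (0, L, 0)
  explore <- function(state, L) {
    tips <- nodes_of_degree(state, 1L)
    expect_identical(sum(census(state) * c(1L, 2L, 3L)), 2L * L)
    if (length(tips) < 2L) {
      expect_equal(unname(census(state)), c(0L, L, 0L))
      return(invisible(NULL))
    }
    pairs <- utils::combn(tips, 2L)
    for (k in seq_len(ncol(pairs)))
      explore(fuse_tip_tip(state, pairs[1L, k], pairs[2L, k]), L)
  }
  for (L in 1:3) explore(network_state(L, "fragmented"), L)
})

test_that("census matches hand counts for the canonical configurations", {
  expect_equal(unname(census(network_state(7, "fragmented"))), c(14L, 0L, 0L))
  expect_equal(unname(census(network_state(12, "loop"))), c(0L, 12L, 0L))
  expect_equal(unname(census(network_state(12, "chain"))), c(2L, 11L, 0L))
})

test_that("edge-list and GraphML snapshots round-trip", {
  set.seed(7)
  state <- random_state(25)
  f <- withr::local_tempfile(fileext = ".edges")
  write_edge_list(state, f)
  back <- read_edge_list(f)
  expect_identical(census(back), census(state))
  expect_identical(oracle_clusters(back), oracle_clusters(state))

  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(state, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(gg), 25)
  expect_equal(sort(as.integer(igraph::degree(gg))),
               sort(as.integer(table(state$node))))
})
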