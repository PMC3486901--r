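# helpers shared across test files: independent census oracles and a
# random-walk generator over the four elementary operations

# applies one uniformly chosen valid operation; returns NULL when none is
random_valid_op <- function(state) {
  cen <- census(state)
  ops <- character(0)
  if (cen[["x1"]] >= 2L) ops <- c(ops, "fuse11")
  if (cen[["x2"]] >= 1L) ops <- c(ops, "fiss2")
  if (cen[["x1"]] >= 1L && cen[["x2"]] >= 1L) ops <- c(ops, "fuse12")
  if (cen[["x3"]] >= 1L) ops <- c(ops, "fiss3")
  if (length(ops) == 0L) return(NULL)
  op <- sample(ops, 1L)
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  switch(op,
    fuse11 = {
      tips <- sample(nodes_of_degree(state, 1L), 2L)
      list(state = fuse_tip_tip(state, tips[1L], tips[2L]),
           delta = c(-2L, 1L, 0L))
    },
    fiss2 = list(state = fiss_tip_tip(state, pick1(nodes_of_degree(state, 2L))),
                 delta = c(2L, -1L, 0L)),
    fuse12 = list(state = fuse_tip_side(state, pick1(nodes_of_degree(state, 1L)),
                                        pick1(nodes_of_degree(state, 2L))),
                  delta = c(-1L, -1L, 1L)),
    fiss3 = {
      br <- pick1(nodes_of_degree(state, 3L))
      edges <- (which(state$node == br) + 1L) %/% 2L
      list(state = fiss_tip_side(state, br, pick1(edges)),
           delta = c(1L, 1L, -1L))
    })
}

# a state reached by n random valid operations from a random start
random_state <- function(L, n_ops = 60L) {
  state <- network_state(L, sample(c("fragmented", "chain", "loop"), 1L))
  for (k in seq_len(n_ops)) {
    step <- random_valid_op(state)
    if (is.null(step)) break
    state <- step$state
  }
  state
}

# independent segment oracle: explicit walk along slots through bulk nodes
# (deliberately different from the igraph component construction in
# segment_census)
oracle_segments <- function(state) {
  L <- state$L
  deg_of <- tabulate(state$node, nbins = max(state$node))
  other_slot_of_node <- function(nid, slot) {
    s <- which(state$node == nid)
    s[s != slot][1L]
  }
  visited <- logical(L)
  out <- list()
  for (slot in seq_len(2L * L)) {
    nid <- state$node[slot]
    if (deg_of[nid] == 2L) next
    e <- (slot + 1L) %/% 2L
    if (visited[e]) next
    cur <- slot
    len <- 0L
    repeat {
      visited[(cur + 1L) %/% 2L] <- TRUE
      len <- len + 1L
      mate <- cur + ifelse(cur %% 2L == 1L, 1L, -1L)
      nid2 <- state$node[mate]
      if (deg_of[nid2] != 2L) {
        out[[length(out) + 1L]] <-
          list(length = len, ends = sort(c(deg_of[nid], deg_of[nid2])))
        break
      }
      cur <- other_slot_of_node(nid2, mate)
    }
  }
  for (e in seq_len(L)) {  # remaining edges form pure loops
    if (visited[e]) next
    cur <- 2L * e - 1L
    len <- 0L
    repeat {
      visited[(cur + 1L) %/% 2L] <- TRUE
      len <- len + 1L
      mate <- cur + ifelse(cur %% 2L == 1L, 1L, -1L)
      cur <- other_slot_of_node(state$node[mate], mate)
      if ((cur + 1L) %/% 2L == e) break
    }
    out[[length(out) + 1L]] <- list(length = len, ends = c(2L, 2L))
  }
  df <- data.frame(length = vapply(out, `[[`, integer(1L), "length"),
                   type = vapply(out, function(s)
                     paste(s$ends, collapse = "-"), character(1L)))
  df[order(df$type, df$length), ]
}

# independent cluster oracle: flood fill over edges through shared nodes
oracle_clusters <- function(state) {
  L <- state$L
  slots_of <- split(seq_len(2L * L), state$node)
  edge_of <- function(s) (s + 1L) %/% 2L
  label <- integer(L)
  comp <- 0L
  for (e0 in seq_len(L)) {
    if (label[e0] != 0L) next
    comp <- comp + 1L
    queue <- e0
    label[e0] <- comp
    while (length(queue) > 0L) {
      e <- queue[1L]
      queue <- queue[-1L]
      for (slot in c(2L * e - 1L, 2L * e)) {
        for (s2 in slots_of[[as.character(state$node[slot])]]) {
          e2 <- edge_of(s2)
          if (label[e2] == 0L) {
            label[e2] <- comp
            queue <- c(queue, e2)
          }
        }
      }
    }
  }
  sort(tabulate(label))
}
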