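#' Reticulum graph state
#'
#' A `network_state` holds `L` persistent edges whose `2L` endpoint slots are
#' partitioned into nodes of degree 1 (tip), 2 (bulk site) or 3 (branching
#' point).  Slot `2e - 1` and slot `2e` are the two ends of edge `e`.  Nodes
#' are ephemeral labels: operations delete the participating nodes and mint
#' fresh identifiers, while edge identities are stable and `L` never changes.
#'
#' @param L number of edges (the divisibility quantum count; one edge
#'   corresponds to about 0.2 micrometres of tubule).
#' @param init initial configuration: `"fragmented"` (L isolated edges),
#'   `"chain"` (one open linear segment) or `"loop"` (one closed loop).
#' @return an object of class `network_state` with fields `L` and `node`
#'   (integer vector of length `2L`, the node id of every slot).
#' @examples
#' s <- network_state(4, "chain")
#' census(s)
#' @export
network_state <- function(L, init = c("fragmented", "chain", "loop")) {
  init <- match.arg(init)
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("L must be a positive integer")
  L <- as.integer(L)
  node <- integer(2L * L)
  if (init == "fragmented") {
    node <- seq_len(2L * L)
  } else {
    # bulk node k joins the right slot of edge k and the left slot of k+1
    for (e in seq_len(L - 1L)) node[c(2L * e, 2L * e + 1L)] <- e
    if (init == "chain") {
      node[1L] <- L
      node[2L * L] <- L + 1L
    } else {
      node[c(2L * L, 1L)] <- L
    }
  }
  new_network_state(L, node)
}

new_network_state <- function(L, node) {
  structure(list(L = as.integer(L), node = as.integer(node)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cen <- census(x)
  cat(sprintf(
    "<network_state> L = %d edges; x1 = %d tips, x2 = %d bulk, x3 = %d branching\n",
    x$L, cen["x1"], cen["x2"], cen["x3"]))
  invisible(x)
}

node_degree <- function(state, id) {
  sum(state$node == id)
}

fresh_ids <- function(state, n) {
  max(state$node) + seq_len(n)
}

#' Node-degree census of a network state
#'
#' Counts nodes of degree 1, 2 and 3.  The counts always satisfy the
#' handshake identity `x1 + 2 x2 + 3 x3 = 2L`.
#'
#' @param state a [network_state()].
#' @return named integer vector `c(x1, x2, x3)`.
#' @export
census <- function(state) {
  stopifnot(inherits(state, "network_state"))
  sizes <- tabulate(tabulate(state$node, nbins = max(state$node)), nbins = 3L)
  c(x1 = sizes[1L], x2 = sizes[2L], x3 = sizes[3L])
}

#' Validate the structural invariants of a network state
#'
#' Checks that every slot belongs to a node of degree 1 to 3 and that the
#' handshake identity holds.
#'
#' @param state a [network_state()].
#' @return `state`, invisibly; errors on violation.
#' @export
validate_network_state <- function(state) {
  stopifnot(inherits(state, "network_state"))
  if (length(state$node) != 2L * state$L)
    stop("slot vector length must be 2L")
  deg <- table(state$node)
  if (any(deg < 1L | deg > 3L))
    stop("node degrees must lie in 1..3")
  cen <- census(state)
  if (cen[["x1"]] + 2L * cen[["x2"]] + 3L * cen[["x3"]] != 2L * state$L)
    stop("handshake identity violated")
  invisible(state)
}

#' Tip-to-tip fusion
#'
#' Merges two distinct degree-1 nodes into one degree-2 bulk node
#' (`x1 - 2`, `x2 + 1`).  Fusing the two ends of the same linear segment is
#' allowed and closes the segment into a disconnected loop; the model is
#' well-mixed and non-spatial.
#'
#' @param state a [network_state()].
#' @param tipA,tipB node ids of two distinct tips.
#' @return the updated `network_state`.
#' @export
fuse_tip_tip <- function(state, tipA, tipB) {
  if (tipA == tipB) stop("tip-to-tip fusion needs two distinct tips")
  if (node_degree(state, tipA) != 1L || node_degree(state, tipB) != 1L)
    stop("tip-to-tip fusion operands must both have degree 1")
  id <- fresh_ids(state, 1L)
  state$node[state$node %in% c(tipA, tipB)] <- id
  state
}

#' Tip-to-tip fission
#'
#' Splits a degree-2 bulk node into two degree-1 tips (`x2 - 1`, `x1 + 2`),
#' the reverse of [fuse_tip_tip()].
#'
#' @param state a [network_state()].
#' @param bulk node id of a degree-2 node.
#' @return the updated `network_state`.
#' @export
fiss_tip_tip <- function(state, bulk) {
  slots <- which(state$node == bulk)
  if (length(slots) != 2L) stop("tip-to-tip fission operand must have degree 2")
  state$node[slots] <- fresh_ids(state, 2L)
  state
}

#' Tip-to-side fusion
#'
#' Merges a degree-1 tip and a degree-2 bulk node into one degree-3
#' branching point (`x1 - 1`, `x2 - 1`, `x3 + 1`).  Intra-segment and
#' intra-cluster fusions are allowed (they create cycles), consistent with
#' the well-mixed assumption.
#'
#' @param state a [network_state()].
#' @param tip node id of a degree-1 node.
#' @param bulk node id of a degree-2 node.
#' @return the updated `network_state`.
#' @export
fuse_tip_side <- function(state, tip, bulk) {
  if (tip == bulk) stop("tip and bulk node must differ")
  if (node_degree(state, tip) != 1L) stop("'tip' must have degree 1")
  if (node_degree(state, bulk) != 2L) stop("'bulk' must have degree 2")
  id <- fresh_ids(state, 1L)
  state$node[state$node %in% c(tip, bulk)] <- id
  state
}

#' Tip-to-side fission
#'
#' Scission across one of the three edges incident to a degree-3 branching
#' point: the chosen edge's slot detaches as a new tip, the remaining two
#' slots form a bulk node (`x3 - 1`, `x2 + 1`, `x1 + 1`).
#'
#' @param state a [network_state()].
#' @param branch node id of a degree-3 node.
#' @param edge_choice id (1..L) of one of the three incident edges.
#' @return the updated `network_state`.
#' @export
fiss_tip_side <- function(state, branch, edge_choice) {
  slots <- which(state$node == branch)
  if (length(slots) != 3L) stop("tip-to-side fission operand must have degree 3")
  det <- slots[(slots + 1L) %/% 2L == edge_choice]
  if (length(det) == 0L) stop("edge_choice is not incident to 'branch'")
  det <- det[1L]  # a 1-edge self-loop on a branch offers the edge twice
  ids <- fresh_ids(state, 2L)
  state$node[det] <- ids[1L]
  state$node[setdiff(slots, det)] <- ids[2L]
  state
}

#' List node ids of a given degree
#'
#' @param state a [network_state()].
#' @param k degree, 1, 2 or 3.
#' @return integer vector of node ids.
#' @export
nodes_of_degree <- function(state, k) {
  deg <- table(state$node)
  as.integer(names(deg)[deg == k])
}

#' Write / read a network snapshot as an edge list
#'
#' Plain-text format, one line per edge: `edge_id node_A node_B`.
#'
#' @param state a [network_state()].
#' @param path file path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a `network_state`.
#' @export
write_edge_list <- function(state, path) {
  stopifnot(inherits(state, "network_state"))
  m <- matrix(state$node, ncol = 2L, byrow = TRUE)
  df <- data.frame(edge = seq_len(state$L), node_a = m[, 1L], node_b = m[, 2L])
  write.table(df, path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, header = TRUE)
  stopifnot(all(c("edge", "node_a", "node_b") %in% names(df)))
  df <- df[order(df$edge), ]
  node <- as.integer(rbind(df$node_a, df$node_b))
  validate_network_state(new_network_state(nrow(df), node))
}

#' Convert a network state to an igraph multigraph
#'
#' Vertices are nodes (vertex attribute `degree` holds the node degree),
#' edges are the reticulum edges (edge attribute `edge_id`).
#'
#' @param state a [network_state()].
#' @return an [igraph::graph].
#' @export
as_igraph <- function(state) {
  stopifnot(inherits(state, "network_state"))
  ids <- sort(unique(state$node))
  m <- matrix(match(state$node, ids), ncol = 2L, byrow = TRUE)
  g <- igraph::make_graph(as.vector(t(m)), n = length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::E(g)$edge_id <- seq_len(state$L)
  g
}

#' Export a network snapshot as GraphML
#'
#' @param state a [network_state()].
#' @param path file path for the GraphML document.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(state, path) {
  igraph::write_graph(as_igraph(state), path, format = "graphml")
  invisible(path)
}
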