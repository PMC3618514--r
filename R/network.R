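# Network containers and graph-theoretical topology.
#
# Two light containers mirror the two edge models: `weighted_network`
# (zero-diagonal symmetric weights in [0,1], the soft-thresholded wavelet
# correlations) and `binary_network` (0/1 adjacency obtained by
# thresholding). All topology parameters (degree, shortest paths, nodal /
# global / local efficiency) are defined on binary graphs.

#' Weighted undirected network
#'
#' @param w square numeric matrix of edge weights in `[0, 1]`, symmetric
#'   with a zero diagonal.
#' @param region_names optional character vector of node labels.
#' @return object of class `weighted_network`: list with `w`, `n_nodes`,
#'   `region_names`.
#' @export
weighted_network <- function(w, region_names = NULL) {
  w <- as.matrix(w)
  check_symmetric_zero_diag(w, "weight matrix")
  if (any(w < 0) || any(w > 1)) {
    stop_invalid("edge weights must lie in [0, 1]")
  }
  if (is.null(region_names)) {
    region_names <- rownames(w)
    if (is.null(region_names)) region_names <- default_region_names(nrow(w))
  }
  stopifnot(length(region_names) == nrow(w))
  dimnames(w) <- list(region_names, region_names)
  structure(
    list(w = w, n_nodes = nrow(w), region_names = region_names),
    class = "weighted_network"
  )
}

#' Binary undirected network
#'
#' @param a square 0/1 adjacency matrix, symmetric with a zero diagonal.
#' @param region_names optional node labels.
#' @return object of class `binary_network`: list with `a`, `n_nodes`,
#'   `m_edges`, `region_names`.
#' @export
binary_network <- function(a, region_names = NULL) {
  a <- as.matrix(a)
  storage.mode(a) <- "integer"
  check_symmetric_zero_diag(a, "adjacency matrix")
  if (!all(a %in% c(0L, 1L))) {
    stop_invalid("adjacency entries must be 0 or 1")
  }
  if (is.null(region_names)) {
    region_names <- rownames(a)
    if (is.null(region_names)) region_names <- default_region_names(nrow(a))
  }
  stopifnot(length(region_names) == nrow(a))
  dimnames(a) <- list(region_names, region_names)
  structure(
    list(
      a = a, n_nodes = nrow(a),
      m_edges = sum(a[upper.tri(a)]),
      region_names = region_names
    ),
    class = "binary_network"
  )
}

#' Maximum number of undirected edges
#'
#' `M_C = N (N - 1) / 2`, the edge count of the complete graph on `n`
#' nodes (11026 for the 149-region system).
#'
#' @param n node count.
#' @return integer edge count.
#' @export
max_edges <- function(n) {
  as.integer(n * (n - 1) / 2)
}

#' Wiring cost (edge density)
#'
#' For a binary graph, `K = M / M_C`; equivalently, and for weighted
#' graphs with weights in `[0, 1]`, the mean of the off-diagonal entries
#' of the (weight) matrix.
#'
#' @param net a `binary_network` or `weighted_network`.
#' @return cost in `[0, 1]`.
#' @export
wiring_cost <- function(net) {
  m <- if (inherits(net, "binary_network")) {
    net$a
  } else if (inherits(net, "weighted_network")) {
    net$w
  } else {
    stop_invalid("net must be a binary_network or weighted_network")
  }
  n <- nrow(m)
  sum(m[upper.tri(m)]) / max_edges(n)
}

#' Node degree
#'
#' Number of edges incident to each node (row sums of the adjacency).
#'
#' @param net a `binary_network`.
#' @return named integer vector `k_i`.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  k <- as.integer(rowSums(net$a))
  names(k) <- net$region_names
  k
}

#' Unweighted shortest path lengths
#'
#' Breadth-first-search hop counts between every node pair; `Inf` marks
#' unreachable pairs, the diagonal is 0.
#'
#' @param net a `binary_network`.
#' @return numeric matrix `l_ij`.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- .all_pairs_distances_cpp(net$a)
  dimnames(d) <- list(net$region_names, net$region_names)
  d
}

#' Nodal efficiency
#'
#' `e_i = (1 / (N - 1)) * sum_{j != i} 1 / l_ij`, with the convention
#' `1 / Inf = 0` for unreachable pairs.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  e <- .binary_metrics_cpp(net$a, FALSE)$efficiency
  names(e) <- net$region_names
  e
}

#' Global efficiency
#'
#' Mean of the nodal efficiencies; a normalised (in `[0, 1]`) measure of
#' parallel information-transfer capacity.
#'
#' @param net a `binary_network`.
#' @return scalar `E_g`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  .binary_metrics_cpp(net$a, FALSE)$global_efficiency
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's
#' neighbour-induced subgraph (node itself removed). Nodes with fewer
#' than two neighbours contribute 0 (their neighbour subgraph has no node
#' pair). Only paths inside the subgraph count.
#'
#' @param net a `binary_network`.
#' @return scalar `E_l` in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  .binary_metrics_cpp(net$a, TRUE)$local_efficiency
}

# Internal: degree / nodal eff / E_g / (optional) E_l from a raw 0/1
# matrix without container overhead; used by the cost-integration loop.
binary_metrics_raw <- function(a, need_local = TRUE) {
  .binary_metrics_cpp(a, need_local)
}

#' Random reference network at a target wiring cost
#'
#' Places exactly `round(cost * M_C)` edges uniformly at random (edge
#' count rounding uses round-half-to-even).
#'
#' @param n node count.
#' @param cost target wiring cost in `[0, 1]`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a `binary_network`.
#' @export
random_network <- function(n, cost, seed = NULL) {
  stopifnot(n >= 2, cost >= 0, cost <= 1)
  mc <- max_edges(n)
  m <- round(cost * mc)
  picked <- with_seed(seed, sample.int(mc, m))
  edge_matrix_from_indices(n, picked)
}

#' Regular (ring-lattice) reference network at a target wiring cost
#'
#' Connects each node to its nearest neighbours on a ring; edges are added
#' in increasing ring distance (ties by node index) until
#' `round(cost * M_C)` edges are placed, so residual edges beyond a full
#' neighbour ring go deterministically to the next ring.
#'
#' @inheritParams random_network
#' @return a `binary_network`.
#' @export
regular_network <- function(n, cost) {
  stopifnot(n >= 2, cost >= 0, cost <= 1)
  mc <- max_edges(n)
  m <- round(cost * mc)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ring_dist <- pmin(abs(ij[, 1] - ij[, 2]), n - abs(ij[, 1] - ij[, 2]))
  ord <- order(ring_dist, ij[, 1], ij[, 2])
  sel <- ord[seq_len(m)]
  a <- matrix(0L, n, n)
  a[ij[sel, , drop = FALSE]] <- 1L
  binary_network(a + t(a))
}

# Build a binary_network from upper-triangle edge indices (column-major
# order of upper.tri, the package's canonical edge enumeration).
edge_matrix_from_indices <- function(n, idx) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut[idx]] <- 1L
  binary_network(a + t(a))
}
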