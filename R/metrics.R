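# Graph-theoretic network measures on binary and weighted connectomes.
#
# All functions accept a Connectome, BinaryConnectome or plain symmetric
# non-negative matrix. Edge weights are treated as connection strengths
# (affinities); shortest-path computations use edge lengths 1/w, the
# standard convention for FA-weighted connectomes, so the binary case
# (weights 0/1) reduces to hop counts. Unreachable pairs contribute zero
# efficiency; characteristic path length returns +Inf when any pair is
# unreachable.

# All-pairs shortest-path distances with lengths 1/w (dense FW in C).
spDistances <- function(W) {
  n <- nrow(W)
  if (n < 2 || sum(W) == 0) {
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    return(D)
  }
  L <- ifelse(W > 0, 1 / W, Inf)
  .cppFwDistances(L)
}

# Global efficiency of a distance matrix.
effFromDistances <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  iv <- 1 / D
  diag(iv) <- 0
  iv[!is.finite(iv)] <- 0
  sum(iv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered node pairs;
#' unreachable pairs contribute zero, so disconnected nodes depress but do
#' not invalidate the measure. Binary networks use hop counts, weighted
#' networks edge lengths 1/w.
#'
#' @param network a \code{Connectome}, \code{BinaryConnectome} or symmetric
#'   non-negative matrix.
#' @return A scalar in [0, 1] for binary input; non-negative for weighted.
#' @export
globalEfficiency <- function(network) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  effFromDistances(spDistances(W))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs. Returns
#' \code{Inf} when any pair is unreachable (e.g. isolated nodes); callers
#' that need a finite panel impute downstream.
#'
#' @inheritParams globalEfficiency
#' @return A positive scalar or \code{Inf}.
#' @export
charPathLength <- function(network) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  n <- nrow(W)
  if (n < 2) return(0)
  D <- spDistances(W)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off))) return(Inf)
  mean(off)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours; nodes with fewer than two neighbours contribute zero.
#' The weighted variant keeps the subgraph's weights and uses lengths 1/w.
#'
#' @inheritParams globalEfficiency
#' @return A non-negative scalar.
#' @export
localEfficiency <- function(network) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  if (nrow(W) == 0) return(0)
  storage.mode(W) <- "double"
  .cppLocalEfficiency(W)
}

#' Clustering coefficient and transitivity
#'
#' Triangle-based segregation measures. Weights are first rescaled by the
#' maximum weight; each triangle contributes the geometric mean of its three
#' rescaled weights, so 0/1 networks reduce to the standard binary
#' clustering coefficient and global transitivity.
#'
#' @inheritParams globalEfficiency
#' @return \code{c(clustering =, transitivity =)}.
#' @export
clusteringTransitivity <- function(network) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  mx <- max(W)
  if (mx == 0) return(c(clustering = 0, transitivity = 0))
  Wh <- (W / mx)^(1 / 3)
  tri <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  c(
    clustering = mean(ci),
    transitivity = if (sum(denom) > 0) sum(tri) / sum(denom) else 0
  )
}

#' Maximized Newman modularity
#'
#' Greedy agglomerative community detection refined by multilevel local
#' moving; the better of the two partitions is reported. Deterministic for a
#' given seed.
#'
#' @inheritParams globalEfficiency
#' @param seed RNG seed controlling the multilevel refinement.
#' @return Modularity Q of the best partition found (0 for edgeless input).
#' @export
modularityQ <- function(network, seed = 42L) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  if (sum(W) == 0) return(0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  wts <- igraph::E(g)$weight
  q1 <- igraph::modularity(igraph::cluster_fast_greedy(g, weights = wts))
  q2 <- withSeed(seed, igraph::modularity(
    igraph::cluster_louvain(g, weights = wts)
  ))
  max(q1, q2)
}

#' Mean node betweenness centrality
#'
#' Shortest-path betweenness with fractional attribution over tied shortest
#' paths, unordered-pair counting, averaged over nodes. Weighted networks
#' route along lengths 1/w.
#'
#' @inheritParams globalEfficiency
#' @return A non-negative scalar.
#' @export
meanBetweenness <- function(network) {
  W <- asWeightMatrix(network)
  stopifnotSquareSym(W, "network")
  if (sum(W) == 0) return(0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  mean(igraph::betweenness(g, weights = 1 / igraph::E(g)$weight))
}

#' Rich-club coefficient
#'
#' For each degree level k, phi(k) is the edge density among the nodes of
#' degree greater than k; the reported value is the mean of phi(k) over the
#' levels retaining at least two nodes. Computed on the binary topology and
#' reported raw (not null-normalized).
#'
#' @param network a \code{BinaryConnectome}, \code{Connectome} (binarized
#'   internally) or matrix.
#' @return Mean rich-club coefficient, or \code{NA} when no level retains
#'   two nodes.
#' @export
richClubCoef <- function(network) {
  A <- (asWeightMatrix(network) > 0) * 1
  stopifnotSquareSym(A, "network")
  k <- rowSums(A)
  if (max(k) < 1) return(NA_real_)
  phis <- numeric(0)
  for (lev in seq_len(max(1, max(k) - 1))) {
    nodes <- which(k > lev)
    N <- length(nodes)
    if (N < 2) next
    E <- sum(A[nodes, nodes]) / 2
    phis <- c(phis, 2 * E / (N * (N - 1)))
  }
  if (length(phis) == 0) return(NA_real_)
  mean(phis)
}

#' Degree assortativity
#'
#' Pearson correlation of degrees at either end of an edge, on the binary
#' topology. \code{NaN} for degree-regular graphs.
#'
#' @inheritParams richClubCoef
#' @return Assortativity coefficient in [-1, 1] (or \code{NaN}).
#' @export
degreeAssortativity <- function(network) {
  A <- (asWeightMatrix(network) > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::assortativity_degree(g)
}
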