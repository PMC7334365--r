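# Degree-preserving null models and normalized efficiencies.
#
# Small-worldness is read off the weighted efficiencies relative to
# degree-matched random networks: Maslov-Sneppen edge swaps randomize the
# binary topology while preserving every node's degree, and the observed
# weight multiset is re-assigned at random onto the rewired edges so the
# weight distribution is preserved as well.

#' Degree-preserving rewiring of a binary topology
#'
#' Maslov-Sneppen edge swaps; the degree sequence is invariant. Graphs with
#' no valid swap (e.g. a triangle) are returned unchanged.
#'
#' @param network binary matrix, \code{BinaryConnectome} or \code{Connectome}
#'   (binarized internally).
#' @param swapsPerEdge attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return A rewired 0/1 adjacency matrix.
#' @export
rewireDegreePreserving <- function(network, swapsPerEdge = 10L, seed = 42L) {
  A <- (asWeightMatrix(network) > 0) * 1
  eu <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(eu) < 2) return(A)
  e2 <- withSeed(seed, .cppRewireEdges(eu, nrow(A),
                                       as.integer(swapsPerEdge) * nrow(eu)))
  An <- matrix(0, nrow(A), ncol(A))
  An[e2] <- 1
  An[e2[, c(2, 1), drop = FALSE]] <- 1
  An
}

# Place a weight multiset randomly onto the edges of a binary topology.
assignWeightsRandomly <- function(A, weightValues, seed) {
  eu <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  W <- matrix(0, nrow(A), ncol(A))
  if (nrow(eu) > 0) {
    wv <- withSeed(seed, sample(weightValues))
    W[eu] <- wv
    W <- W + t(W)
  }
  W
}

#' Generate a degree-preserving null ensemble
#'
#' For each null: rewire the binary topology with Maslov-Sneppen swaps, then
#' re-assign the observed weight multiset randomly onto the rewired edges;
#' record the null's weighted global and local efficiency.
#'
#' @param connectome a \code{Connectome} (or weight matrix); binary input
#'   yields unit weights.
#' @param nNulls number of nulls (default 100).
#' @param swapsPerEdge attempted swaps per edge (default 10).
#' @param seed base RNG seed; each null uses a derived child seed.
#' @return A \code{\linkS4class{NullEnsemble}}.
#' @export
degreePreservingNulls <- function(connectome, nNulls = 100L,
                                  swapsPerEdge = 10L, seed = 42L) {
  W <- asWeightMatrix(connectome)
  stopifnotSquareSym(W, "connectome")
  A <- (W > 0) * 1
  wvals <- W[upper.tri(W) & W > 0]
  ge <- le <- numeric(nNulls)
  for (b in seq_len(nNulls)) {
    sA <- childSeed(seed, 2L * b - 1L)
    sW <- childSeed(seed, 2L * b)
    An <- rewireDegreePreserving(A, swapsPerEdge, sA)
    Wn <- assignWeightsRandomly(An, wvals, sW)
    ge[b] <- globalEfficiency(Wn)
    le[b] <- localEfficiency(Wn)
  }
  new("NullEnsemble",
    nNulls = as.integer(nNulls), swapsPerEdge = as.integer(swapsPerEdge),
    seed = as.integer(seed), globalEff = ge, localEff = le
  )
}

#' Null-normalized weighted efficiencies
#'
#' Observed weighted global and local efficiency divided by the
#' corresponding null-ensemble means. A small-world network has normalized
#' local efficiency above 1 and normalized global efficiency below 1.
#'
#' @param connectome a \code{Connectome} or weight matrix.
#' @param ensemble a \code{NullEnsemble} built from the same network, or
#'   \code{NULL} to build one.
#' @param ... passed to \code{\link{degreePreservingNulls}} when
#'   \code{ensemble} is \code{NULL}.
#' @return \code{c(normGlobal =, normLocal =)}; \code{NaN} when the null
#'   means vanish (edgeless networks).
#' @export
normalizedEfficiencies <- function(connectome, ensemble = NULL, ...) {
  W <- asWeightMatrix(connectome)
  if (is.null(ensemble)) ensemble <- degreePreservingNulls(W, ...)
  mg <- mean(ensemble@globalEff)
  ml <- mean(ensemble@localEff)
  if (!is.finite(mg) || !is.finite(ml) || mg == 0 || ml == 0) {
    if (ensemble@nNulls > 0L)
      warning("null-ensemble mean efficiency is zero; normalization undefined")
    mg <- ml <- NA_real_
  }
  c(
    normGlobal = globalEfficiency(W) / mg,
    normLocal = localEfficiency(W) / ml
  )
}

# Canonical order of the 21-measure panel.
metricNames <- function() {
  c(
    "density", "mean_degree", "global_efficiency_b", "local_efficiency_b",
    "char_path_length_b", "clustering_b", "transitivity_b", "modularity_b",
    "betweenness_b", "mean_strength", "global_efficiency_w",
    "local_efficiency_w", "char_path_length_w", "clustering_w",
    "transitivity_w", "modularity_w", "betweenness_w", "assortativity",
    "rich_club", "norm_global_efficiency", "norm_local_efficiency"
  )
}

#' Compute the full 21-measure panel
#'
#' Nine binary measures (density, mean degree, global/local efficiency,
#' characteristic path length, clustering, transitivity, modularity, mean
#' betweenness), eight weighted counterparts (mean strength replacing
#' density/degree), degree assortativity, the raw rich-club coefficient, and
#' the two null-normalized weighted efficiencies. Characteristic path
#' lengths carry an \code{Inf} sentinel when the network has disconnected
#' nodes; the \code{"disconnected"} attribute flags such subjects.
#'
#' @param connectome a \code{Connectome} (or weight matrix).
#' @param nNulls nulls for the normalized efficiencies (default 100).
#' @param swapsPerEdge swaps per edge in the null rewiring (default 10).
#' @param seed RNG seed for modularity refinement and the null ensemble.
#' @return A named numeric vector of length 21 with attribute
#'   \code{disconnected} (logical).
#' @export
computeAllMetrics <- function(connectome, nNulls = 100L, swapsPerEdge = 10L,
                              seed = 42L) {
  W <- asWeightMatrix(connectome)
  stopifnotSquareSym(W, "connectome")
  A <- (W > 0) * 1
  n <- nrow(W)
  k <- rowSums(A)
  ctB <- clusteringTransitivity(A)
  ctW <- clusteringTransitivity(W)
  ens <- degreePreservingNulls(W, nNulls = nNulls,
                               swapsPerEdge = swapsPerEdge, seed = seed)
  ne <- normalizedEfficiencies(W, ens)
  cplB <- charPathLength(A)
  out <- c(
    density = sum(A) / (n * (n - 1)),
    mean_degree = mean(k),
    global_efficiency_b = globalEfficiency(A),
    local_efficiency_b = localEfficiency(A),
    char_path_length_b = cplB,
    clustering_b = unname(ctB["clustering"]),
    transitivity_b = unname(ctB["transitivity"]),
    modularity_b = modularityQ(A, seed = seed),
    betweenness_b = meanBetweenness(A),
    mean_strength = mean(rowSums(W)),
    global_efficiency_w = globalEfficiency(W),
    local_efficiency_w = localEfficiency(W),
    char_path_length_w = charPathLength(W),
    clustering_w = unname(ctW["clustering"]),
    transitivity_w = unname(ctW["transitivity"]),
    modularity_w = modularityQ(W, seed = seed),
    betweenness_w = meanBetweenness(W),
    assortativity = degreeAssortativity(A),
    rich_club = richClubCoef(A),
    norm_global_efficiency = unname(ne["normGlobal"]),
    norm_local_efficiency = unname(ne["normLocal"])
  )
  attr(out, "disconnected") <- !is.finite(cplB)
  out
}

#' Impute characteristic-path-length sentinels across a cohort
#'
#' Replaces \code{Inf} characteristic path lengths by the cohort maximum of
#' the finite values, column-wise, so the panel can enter regression models.
#'
#' @param metricsMatrix subjects x measures matrix (columns named as in
#'   \code{computeAllMetrics}).
#' @return The matrix with sentinels imputed.
#' @export
imputePathLengthSentinels <- function(metricsMatrix) {
  for (cl in c("char_path_length_b", "char_path_length_w")) {
    if (!cl %in% colnames(metricsMatrix)) next
    v <- metricsMatrix[, cl]
    bad <- !is.finite(v)
    if (any(bad) && any(!bad)) metricsMatrix[bad, cl] <- max(v[!bad])
  }
  metricsMatrix
}
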