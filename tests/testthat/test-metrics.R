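test_that("global efficiency matches hand-computed examples", {
  expect_equal(globalEfficiency(completeGraph(4)), 1)
  expect_equal(globalEfficiency(pathGraph3()), 5 / 6)  # distances 1,1,2
  expect_equal(globalEfficiency(matrix(0, 2, 2)), 0)   # disconnected pair
})

test_that("characteristic path length diverges on disconnected graphs", {
  expect_equal(charPathLength(pathGraph3()), 4 / 3)
  expect_equal(charPathLength(completeGraph(4)), 1)
  A <- completeGraph(4)
  A[4, ] <- A[, 4] <- 0  # isolate a node
  expect_equal(charPathLength(A), Inf)
})

test_that("local efficiency follows the neighbourhood-subgraph definition", {
  expect_equal(localEfficiency(completeGraph(4)), 1)
  expect_equal(localEfficiency(starGraph(3)), 0)
  W <- randomGraph(10, 0.4, weighted = TRUE, seed = 7)
  expect_equal(localEfficiency(W), bfLocalEff(W))
})

test_that("clustering and transitivity match triangle enumeration", {
  expect_equal(clusteringTransitivity(completeGraph(3)),
               c(clustering = 1, transitivity = 1))
  expect_equal(clusteringTransitivity(starGraph(4)),
               c(clustering = 0, transitivity = 0))
  A <- randomGraph(12, 0.35, seed = 11)
  expect_equal(clusteringTransitivity(A), bfClustTrans(A))
  W <- randomGraph(12, 0.35, weighted = TRUE, seed = 12)
  expect_equal(clusteringTransitivity(W), bfClustTrans(W))
})

test_that("modularity finds the planted two-community structure", {
  # two disjoint triangles: optimal partition is the components, Q = 0.5
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- completeGraph(3)
  A[4:6, 4:6] <- completeGraph(3)
  expect_equal(modularityQ(A), 0.5)
  expect_equal(modularityOf(A, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularityQ(completeGraph(6)), 0)
  # never worse than a naive spectral bisection
  for (s in 1:5) {
    W <- randomGraph(12, 0.3, weighted = s %% 2 == 0, seed = 100 + s)
    expect_gte(modularityQ(W) + 1e-9, spectralSplitQ(W))
  }
})

test_that("betweenness matches exhaustive path enumeration", {
  expect_equal(meanBetweenness(pathGraph3()), 1 / 3)  # middle node carries 1
  expect_equal(meanBetweenness(completeGraph(4)), 0)
  for (s in 1:3) {
    W <- randomGraph(10, 0.35, weighted = s == 3, seed = 200 + s)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(meanBetweenness(W), mean(bfBetweenness(W)), tolerance = 1e-9)
  }
})

test_that("rich club matches direct subgraph counting", {
  expect_equal(richClubCoef(completeGraph(4)), 1)
  expect_true(is.na(richClubCoef(starGraph(3))))  # no level keeps 2 nodes
  for (s in 1:3) {
    A <- randomGraph(12, 0.4, seed = 300 + s)
    expect_equal(richClubCoef(A), bfRichClub(A))
  }
})

test_that("binary metrics ignore weight rescaling; weighted efficiency is linear", {
  W <- randomGraph(12, 0.4, weighted = TRUE, seed = 21)
  A <- (W > 0) * 1
  expect_equal((5 * W > 0) * 1, A)
  expect_equal(globalEfficiency(3 * W), 3 * globalEfficiency(W))
  expect_equal(localEfficiency(3 * W), 3 * localEfficiency(W))
  expect_equal(charPathLength(3 * W), charPathLength(W) / 3)
  expect_equal(clusteringTransitivity(3 * W), clusteringTransitivity(W))
})

test_that("global efficiency dominates the inverse path length (Jensen)", {
  for (s in 1:10) {
    A <- randomGraph(9, 0.5, seed = 400 + s)
    L <- charPathLength(A)
    if (!is.finite(L)) next
    expect_gte(globalEfficiency(A), 1 / L)
  }
})

test_that("the full panel has 21 named entries and flags disconnection", {
  cfg <- simulationConfig()
  cn <- simulateConnectome(cfg, 0.3, seed = 4L)
  v <- computeAllMetrics(cn, nNulls = 5L, seed = 1L)
  expect_length(v, 21)
  expect_named(v)
  expect_false(attr(v, "disconnected"))
  expect_true(all(is.finite(v)))
  # isolate a node: path lengths diverge, flag set, everything else finite
  W <- connWeights(cn)
  W[1, ] <- W[, 1] <- 0
  v2 <- computeAllMetrics(W, nNulls = 5L, seed = 1L)
  expect_true(attr(v2, "disconnected"))
  expect_equal(unname(v2["char_path_length_b"]), Inf)
  expect_true(all(is.finite(v2[setdiff(names(v2), c("char_path_length_b",
                                                    "char_path_length_w"))])))
})

test_that("the panel is invariant to node relabelling", {
  cfg <- simulationConfig(nNodes = 30L, baseDegree = 6L)
  cn <- simulateConnectome(cfg, 0.2, seed = 9L)
  W <- connWeights(cn)
  set.seed(5)
  p <- sample(nrow(W))
  v1 <- computeAllMetrics(W, nNulls = 0L, seed = 1L)
  v2 <- computeAllMetrics(W[p, p], nNulls = 0L, seed = 1L)
  # modularity search is a heuristic whose partition may depend on label
  # order; its Q values agree only approximately under relabelling
  exact <- !grepl("norm_|modularity", names(v1))
  expect_equal(v1[exact], v2[exact], tolerance = 1e-9)
  expect_equal(v1[grepl("modularity", names(v1))],
               v2[grepl("modularity", names(v2))], tolerance = 0.05)
})

test_that("path-length sentinels are imputed by the cohort maximum", {
  M <- cbind(char_path_length_b = c(2, Inf, 3), char_path_length_w = c(5, 6, Inf),
             other = c(1, 2, 3))
  M2 <- imputePathLengthSentinels(M)
  expect_equal(unname(M2[2, "char_path_length_b"]), 3)
  expect_equal(unname(M2[3, "char_path_length_w"]), 6)
  expect_equal(unname(M2[, "other"]), unname(M[, "other"]))
})
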