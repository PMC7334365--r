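# helpers building streamline sets and parcellations in code
mkParc <- function(nRegions = 2) {
  labels <- array(0L, c(6, 3, 3))
  labels[1, , ] <- 1L
  labels[6, , ] <- 2L
  if (nRegions >= 3) labels[3, 1, 1] <- 3L
  parcellation(labels, voxelSize = 1, nRegions = nRegions,
               regionVolumes = rep(1000, nRegions))  # 1 cm^3 each
}

mkStreamline <- function(x0, x1, meanFA) {
  list(points = rbind(c(x0, 0.5, 0.5), c((x0 + x1) / 2, 0.5, 0.5),
                      c(x1, 0.5, 0.5)), meanFA = meanFA)
}

mkSet <- function(...) {
  new("StreamlineSet", streamlines = list(...), sourceId = "test")
}

test_that("endpoint assignment follows the containment rules", {
  parc <- mkParc(3)
  asg <- assignEndpoints(mkSet(
    mkStreamline(0.5, 5.5, 0.5),   # parcels 1 -> 2
    mkStreamline(1.5, 5.5, 0.5),   # background start -> unassigned
    mkStreamline(0.2, 0.8, 0.5)    # both ends in parcel 1 -> unassigned
  ), parc)
  expect_equal(asg$regionA[1], 1)
  expect_equal(asg$regionB[1], 2)
  expect_true(is.na(asg$regionA[2]))
  expect_true(is.na(asg$regionA[3]))
})

test_that("edge weights follow mean-FA x count over mean endpoint volume", {
  parc <- mkParc(2)
  cn <- buildConnectome(mkSet(
    mkStreamline(0.5, 5.5, 0.4),
    mkStreamline(0.5, 5.5, 0.6)
  ), parc)
  # raw = mean FA (0.5) * 2 streamlines = 1.0; volumes 1 cm^3 -> weight 1.0
  expect_equal(connWeights(cn)[1, 2], 1.0)
  expect_equal(streamlineCounts(cn)[1, 2], 2L)
  expect_equal(diag(connWeights(cn)), c(0, 0))
})

test_that("empty streamline sets give the all-zero matrix", {
  cn <- buildConnectome(mkSet(), mkParc(2))
  expect_true(all(connWeights(cn) == 0))
})

test_that("raw weights are linear in streamline count at fixed mean FA", {
  parc <- mkParc(2)
  one <- list(mkStreamline(0.5, 5.5, 0.4), mkStreamline(0.5, 5.5, 0.6))
  cn1 <- buildConnectome(do.call(mkSet, one), parc)
  cn2 <- buildConnectome(do.call(mkSet, c(one, one)), parc)
  expect_equal(connWeights(cn2)[1, 2], 2 * connWeights(cn1)[1, 2])
})

test_that("scaling region volumes by c scales weights by 1/c", {
  labels <- mkParc(2)@labels
  p1 <- parcellation(labels, voxelSize = 1, nRegions = 2,
                     regionVolumes = c(1000, 1000))
  p3 <- parcellation(labels, voxelSize = 1, nRegions = 2,
                     regionVolumes = 3 * c(1000, 1000))
  s <- mkSet(mkStreamline(0.5, 5.5, 0.5))
  w1 <- connWeights(buildConnectome(s, p1))[1, 2]
  w3 <- connWeights(buildConnectome(s, p3))[1, 2]
  expect_equal(w3, w1 / 3)
})

test_that("volume normalization variants differ as documented", {
  parc <- mkParc(2)
  s <- mkSet(mkStreamline(0.5, 5.5, 0.5))
  wMean <- connWeights(buildConnectome(s, parc, "mean"))[1, 2]
  wSum <- connWeights(buildConnectome(s, parc, "sum"))[1, 2]
  expect_equal(wSum, wMean / 2)
})

test_that("binarization keeps any positive weight and is scale invariant", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1e-9
  cn <- new("Connectome", weights = W, nodeVolumes = rep(1000, 3),
            streamlineCounts = matrix(0L, 3, 3))
  A <- adjacency(binarize(cn))
  expect_equal(A[1, 2], 1)
  expect_equal(sum(A), 2)
  cn5 <- new("Connectome", weights = 5 * W, nodeVolumes = rep(1000, 3),
             streamlineCounts = matrix(0L, 3, 3))
  expect_equal(adjacency(binarize(cn5)), A)
  expect_true(all(adjacency(binarize(0 * W)) == 0))
})

test_that("connectome TSV I/O preserves weights to high precision", {
  dir <- withr::local_tempdir()
  W <- randomGraph(12, 0.4, weighted = TRUE, seed = 3)
  cn <- new("Connectome", weights = W, nodeVolumes = rep(1000, 12),
            streamlineCounts = matrix(as.integer(W > 0), 12, 12))
  p <- file.path(dir, "adj.tsv")
  writeConnectomeTSV(cn, p)
  cn2 <- readConnectomeTSV(p)
  expect_equal(connWeights(cn2), W, tolerance = 1e-9)
})

test_that("phantom-derived connectome has exactly one connected pair", {
  ph <- makeBundlePhantom(c(16, 9, 9))
  cn <- buildConnectome(trackAll(ph), phantomParcellation(ph))
  W <- connWeights(cn)
  expect_equal(sum(W[upper.tri(W)] > 0), 1)
})
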