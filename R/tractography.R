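# Deterministic FACT-style tractography on tensor-field phantoms.
#
# Propagation is fixed-step with nearest-voxel direction lookup: at every
# step the point advances `stepSize` mm along the principal direction of the
# voxel it currently occupies, sign-aligned with the previous step. This is
# an approximation to classical voxel-boundary-crossing FACT; with the
# default step of half a voxel no voxel is skipped along axis-aligned
# bundles. A branch terminates when it leaves the mask, enters a voxel with
# FA below the stop threshold, the turning angle between the principal
# directions of successive distinct voxels exceeds the limit, or the step
# cap is reached. Within-voxel steps never trigger the angle rule.

voxelOf <- function(point, voxelSize) as.integer(floor(point / voxelSize)) + 1L

voxelCenter <- function(idx, voxelSize) (idx - 0.5) * voxelSize

insideGrid <- function(idx, dims) all(idx >= 1L) && all(idx <= dims)

#' Seed positions for tractography
#'
#' One seed at the center of every masked voxel whose FA exceeds the start
#' threshold. An empty mask yields an empty seed list with a message, not an
#' error.
#'
#' @param phantom a \code{TensorFieldPhantom}.
#' @param params a \code{TrackingParams}.
#' @return A matrix with one row per seed: voxel indices \code{i, j, k} and
#'   world coordinates \code{x, y, z} in mm, ordered by voxel index
#'   (column-major).
#' @export
seedVoxels <- function(phantom, params = trackingParams(voxelSize = phantom@voxelSize)) {
  ok <- phantom@mask & (phantom@fa > params@faStartThreshold)
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    message("seedVoxels: no voxel exceeds the FA start threshold")
    return(matrix(numeric(0), ncol = 6,
                  dimnames = list(NULL, c("i", "j", "k", "x", "y", "z"))))
  }
  xyz <- voxelCenter(idx, phantom@voxelSize)
  out <- cbind(idx, xyz)
  colnames(out) <- c("i", "j", "k", "x", "y", "z")
  out
}

# Propagate one branch from the seed voxel along initial direction dir0.
# Returns list(points = n x 3 matrix (possibly 0 rows), voxels = visited
# voxel indices beyond the seed).
trackBranch <- function(phantom, seedIdx, dir0, params) {
  dims <- dim(phantom@fa)
  vs <- phantom@voxelSize
  pos <- voxelCenter(seedIdx, vs)
  curVox <- seedIdx
  curDir <- dir0
  pts <- matrix(numeric(0), ncol = 3)
  voxes <- matrix(integer(0), ncol = 3)
  cosLimit <- cos(params@maxTurnAngle * pi / 180)
  for (step in seq_len(params@maxSteps)) {
    newPos <- pos + params@stepSize * curDir
    v <- voxelOf(newPos, vs)
    # mask (or grid) exit ends the branch at the last in-mask point, so
    # endpoints always remain assignable to a parcel
    if (!insideGrid(v, dims) || !phantom@mask[v[1], v[2], v[3]]) break
    if (!all(v == curVox)) {
      if (phantom@fa[v[1], v[2], v[3]] < params@faStopThreshold) break
      dnew <- phantom@directions[v[1], v[2], v[3], ]
      if (sum(dnew^2) == 0) break
      dp <- sum(dnew * curDir)
      if (dp < 0) {
        dnew <- -dnew
        dp <- -dp
      }
      if (dp < cosLimit - 1e-12) break
      curVox <- v
      curDir <- dnew
      voxes <- rbind(voxes, v)
    }
    pts <- rbind(pts, newPos)
    pos <- newPos
  }
  list(points = pts, voxels = voxes)
}

#' Track a single streamline from a seed voxel
#'
#' Bidirectional propagation (unless disabled in \code{params}) from the
#' center of the seed voxel along the voxel's principal direction; the two
#' branches are concatenated as reversed negative branch, seed center,
#' positive branch. The streamline's mean FA is averaged over the sequence
#' of distinct voxels visited.
#'
#' @param phantom a \code{TensorFieldPhantom}.
#' @param seedIdx integer voxel index vector \code{c(i, j, k)}.
#' @param params a \code{TrackingParams}.
#' @return A streamline record: \code{list(points, meanFA)}, or \code{NULL}
#'   when fewer than two points could be generated (degenerate seeds).
#' @export
trackFiber <- function(phantom, seedIdx,
                       params = trackingParams(voxelSize = phantom@voxelSize)) {
  seedIdx <- as.integer(seedIdx)
  dims <- dim(phantom@fa)
  if (!insideGrid(seedIdx, dims) ||
      !phantom@mask[seedIdx[1], seedIdx[2], seedIdx[3]])
    stop("seed voxel outside mask")
  if (phantom@fa[seedIdx[1], seedIdx[2], seedIdx[3]] <= params@faStartThreshold)
    stop("seed voxel FA at or below the start threshold")
  d0 <- phantom@directions[seedIdx[1], seedIdx[2], seedIdx[3], ]
  if (sum(d0^2) == 0) stop("seed voxel has no principal direction")

  bPos <- trackBranch(phantom, seedIdx, d0, params)
  pts <- rbind(voxelCenter(seedIdx, phantom@voxelSize), bPos$points)
  voxSeq <- rbind(seedIdx, bPos$voxels)
  if (params@bidirectional) {
    bNeg <- trackBranch(phantom, seedIdx, -d0, params)
    if (nrow(bNeg$points) > 0)
      pts <- rbind(bNeg$points[rev(seq_len(nrow(bNeg$points))), , drop = FALSE],
                   pts)
    voxSeq <- rbind(bNeg$voxels, voxSeq)
  }
  if (nrow(pts) < 2L) return(NULL)
  # canonical orientation (lexicographically smaller endpoint first) so the
  # output is invariant to a global sign flip of the direction field
  a <- pts[1, ]
  b <- pts[nrow(pts), ]
  cmp <- sign(a - b)
  first <- cmp[cmp != 0]
  if (length(first) && first[1] > 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  keyed <- unique(voxSeq)
  faVals <- phantom@fa[keyed]
  list(points = unname(pts), meanFA = mean(faVals))
}

#' Track streamlines from every seed voxel
#'
#' Applies \code{\link{trackFiber}} to every seed returned by
#' \code{\link{seedVoxels}}, in deterministic voxel-index order. Seeds that
#' fail (degenerate direction fields) are skipped and counted.
#'
#' @param phantom a \code{TensorFieldPhantom}.
#' @param params a \code{TrackingParams}.
#' @param sourceId provenance tag stored on the result.
#' @return A \code{\linkS4class{StreamlineSet}}.
#' @export
trackAll <- function(phantom,
                     params = trackingParams(voxelSize = phantom@voxelSize),
                     sourceId = "phantom") {
  seeds <- seedVoxels(phantom, params)
  out <- list()
  skipped <- 0L
  for (r in seq_len(nrow(seeds))) {
    sl <- tryCatch(
      trackFiber(phantom, seeds[r, 1:3], params),
      error = function(e) NULL
    )
    if (is.null(sl)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- sl
  }
  if (skipped > 0L)
    message(sprintf("trackAll: skipped %d degenerate seed(s)", skipped))
  new("StreamlineSet", streamlines = out, sourceId = sourceId)
}

#' Write streamlines in a line-delimited text format
#'
#' Each record is a header line \code{# <id> <meanFA> <nPoints>} followed by
#' \code{nPoints} rows of \code{x y z} in mm.
#'
#' @param sset a \code{StreamlineSet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeStreamlines <- function(sset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#source %s", sset@sourceId), con)
  for (i in seq_along(sset@streamlines)) {
    s <- sset@streamlines[[i]]
    writeLines(sprintf("# %d %.10g %d", i, s$meanFA, nrow(s$points)), con)
    utils::write.table(format(s$points, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read streamlines written by \code{writeStreamlines}
#'
#' @param path input file.
#' @return A \code{StreamlineSet}.
#' @export
readStreamlines <- function(path) {
  lines <- readLines(path)
  src <- sub("^#source ", "", lines[1])
  i <- 2L
  out <- list()
  while (i <= length(lines)) {
    hdr <- strsplit(sub("^# ", "", lines[i]), " +")[[1]]
    np <- as.integer(hdr[3])
    block <- lines[(i + 1L):(i + np)]
    pts <- do.call(rbind, lapply(strsplit(trimws(block), " +"),
                                 function(x) as.numeric(x)))
    out[[length(out) + 1L]] <- list(points = pts, meanFA = as.numeric(hdr[2]))
    i <- i + np + 1L
  }
  new("StreamlineSet", streamlines = out, sourceId = src)
}
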