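# Connectome construction: map streamline endpoints onto a parcellation and
# aggregate FA-weighted, volume-normalized connection strengths into an
# undirected weighted matrix.

#' Build a parcellation from a label volume
#'
#' Region volumes are computed as voxel counts times the voxel volume unless
#' supplied explicitly.
#'
#' @param labels integer 3-D array of parcel ids (0 = background).
#' @param voxelSize voxel edge length in mm.
#' @param nRegions number of regions; defaults to \code{max(labels)}.
#' @param regionNames optional region names; default \code{"R1"..}.
#' @param regionVolumes optional region volumes in mm^3.
#' @return A \code{\linkS4class{Parcellation}}.
#' @export
parcellation <- function(labels, voxelSize = 2.5, nRegions = NULL,
                         regionNames = NULL, regionVolumes = NULL) {
  labels <- array(as.integer(labels), dim = dim(labels))
  R <- if (is.null(nRegions)) max(labels) else as.integer(nRegions)
  if (is.null(regionVolumes)) {
    counts <- tabulate(labels[labels > 0L], nbins = R)
    regionVolumes <- counts * voxelSize^3
  }
  if (is.null(regionNames)) regionNames <- paste0("R", seq_len(R))
  new("Parcellation",
    labels = labels, regionVolumes = as.numeric(regionVolumes),
    regionNames = regionNames, voxelSize = voxelSize
  )
}

#' Parcellation of a phantom's own label volume
#'
#' @param phantom a \code{TensorFieldPhantom}.
#' @param nRegions optional region count.
#' @return A \code{Parcellation} sharing the phantom's grid and voxel size.
#' @export
phantomParcellation <- function(phantom, nRegions = NULL) {
  parcellation(phantom@labels, voxelSize = phantom@voxelSize,
               nRegions = nRegions)
}

#' Assign streamline endpoints to parcels
#'
#' The first and last point of each streamline are mapped to the parcel of
#' their containing voxel (nearest-voxel containment, no dilation). A
#' streamline contributes to the network only when both endpoints fall in
#' non-zero, distinct parcels; endpoints in the background, outside the
#' grid, or in the same parcel leave the streamline unassigned.
#'
#' @param sset a \code{StreamlineSet}.
#' @param parc a \code{Parcellation} in the same coordinate frame.
#' @return A data.frame with one row per streamline: \code{regionA},
#'   \code{regionB} (NA when unassigned) and \code{meanFA}.
#' @export
assignEndpoints <- function(sset, parc) {
  dims <- dim(parc@labels)
  vs <- parc@voxelSize
  lookup <- function(p) {
    v <- voxelOf(p, vs)
    if (!insideGrid(v, dims)) return(NA_integer_)
    parc@labels[v[1], v[2], v[3]]
  }
  n <- length(sset@streamlines)
  ra <- rb <- integer(n)
  fa <- numeric(n)
  for (i in seq_len(n)) {
    s <- sset@streamlines[[i]]
    a <- lookup(s$points[1, ])
    b <- lookup(s$points[nrow(s$points), ])
    ok <- !is.na(a) && !is.na(b) && a > 0L && b > 0L && a != b
    ra[i] <- if (ok) a else NA_integer_
    rb[i] <- if (ok) b else NA_integer_
    fa[i] <- s$meanFA
  }
  data.frame(regionA = ra, regionB = rb, meanFA = fa)
}

#' Build a weighted connectome from streamlines
#'
#' For every region pair the raw connection strength is the mean FA of the
#' connecting streamlines multiplied by their number; the edge weight then
#' normalizes this strength by the endpoint-region volumes (in cm^3). The
#' default normalizer is the mean of the two region volumes; the cited
#' normalization scheme is ambiguous between one volume, the sum and the
#' mean, so the variant is exposed.
#'
#' @param sset a \code{StreamlineSet}.
#' @param parc a \code{Parcellation}.
#' @param volumeNorm one of \code{"mean"}, \code{"sum"},
#'   \code{"product-root"}.
#' @return A \code{\linkS4class{Connectome}} of order
#'   \code{length(regionVolumes(parc))}.
#' @export
buildConnectome <- function(sset, parc, volumeNorm = c("mean", "sum",
                                                       "product-root")) {
  volumeNorm <- match.arg(volumeNorm)
  R <- length(parc@regionVolumes)
  asg <- assignEndpoints(sset, parc)
  asg <- asg[!is.na(asg$regionA), , drop = FALSE]
  nDropped <- length(sset@streamlines) - nrow(asg)
  if (nDropped > 0)
    message(sprintf("buildConnectome: %d unassigned streamline(s)", nDropped))
  counts <- matrix(0L, R, R)
  faSum <- matrix(0, R, R)
  for (i in seq_len(nrow(asg))) {
    a <- min(asg$regionA[i], asg$regionB[i])
    b <- max(asg$regionA[i], asg$regionB[i])
    counts[a, b] <- counts[a, b] + 1L
    faSum[a, b] <- faSum[a, b] + asg$meanFA[i]
  }
  volCm3 <- parc@regionVolumes / 1000
  if (any(volCm3 <= 0 & (rowSums(counts) + colSums(counts)) > 0))
    stop("connected region with zero volume")
  W <- matrix(0, R, R)
  up <- which(counts > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(up))) {
    a <- up[r, 1]; b <- up[r, 2]
    raw <- faSum[a, b]  # mean FA * count == sum of meanFA over streamlines
    denom <- switch(volumeNorm,
      "mean" = (volCm3[a] + volCm3[b]) / 2,
      "sum" = volCm3[a] + volCm3[b],
      "product-root" = sqrt(volCm3[a] * volCm3[b])
    )
    W[a, b] <- raw / denom
  }
  W <- W + t(W)
  counts <- counts + t(counts)
  new("Connectome",
    weights = W, nodeVolumes = parc@regionVolumes,
    streamlineCounts = counts
  )
}

#' Binarize a weighted connectome
#'
#' Any strictly positive weight becomes an edge.
#'
#' @param connectome a \code{Connectome} or weight matrix.
#' @return A \code{\linkS4class{BinaryConnectome}}.
#' @export
binarize <- function(connectome) {
  W <- asWeightMatrix(connectome)
  new("BinaryConnectome", adjacency = (W > 0) * 1)
}

#' Write a connectome weight matrix as TSV
#'
#' Full square matrix with a header of node names, at full double precision.
#'
#' @param connectome a \code{Connectome}, \code{BinaryConnectome} or matrix.
#' @param path output file.
#' @param nodeNames optional node names (default \code{"R1"..}).
#' @return Invisibly, \code{path}.
#' @export
writeConnectomeTSV <- function(connectome, path, nodeNames = NULL) {
  W <- asWeightMatrix(connectome)
  if (is.null(nodeNames)) nodeNames <- paste0("R", seq_len(nrow(W)))
  df <- as.data.frame(formatC(W, digits = 12, format = "g"))
  names(df) <- nodeNames
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectome weight matrix from TSV
#'
#' @param path file written by \code{\link{writeConnectomeTSV}}.
#' @param nodeVolumes optional node volumes (mm^3); defaults to 1 cm^3 each.
#' @return A \code{Connectome} (streamline counts unknown, set to zero where
#'   weights are zero and one otherwise).
#' @export
readConnectomeTSV <- function(path, nodeVolumes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  W <- unname(as.matrix(df))
  storage.mode(W) <- "double"
  W <- (W + t(W)) / 2  # guard against formatting asymmetry
  diag(W) <- 0
  if (is.null(nodeVolumes)) nodeVolumes <- rep(1000, nrow(W))
  new("Connectome",
    weights = W, nodeVolumes = nodeVolumes,
    streamlineCounts = matrix(as.integer(W > 0), nrow(W), ncol(W))
  )
}
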