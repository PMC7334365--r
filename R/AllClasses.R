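#' @import methods
NULL

#' Tensor-field phantom
#'
#' A minimal tensor-field volume for deterministic tractography: a fractional
#' anisotropy (FA) grid, a principal diffusion direction per voxel, a brain
#' mask and an integer parcel label per voxel. Geometry is axis-aligned with
#' isotropic voxels; the world coordinate of the center of voxel
#' \code{(i, j, k)} (1-based) is \code{(c(i, j, k) - 0.5) * voxelSize} mm.
#'
#' @slot fa numeric 3-D array of FA values in [0, 1].
#' @slot directions numeric 4-D array (dim x dim x dim x 3) of unit principal
#'   direction vectors; may be zero outside the mask.
#' @slot mask logical 3-D array, \code{TRUE} inside the trackable volume.
#' @slot labels integer 3-D array of parcel ids (0 = background).
#' @slot voxelSize numeric scalar, voxel edge length in mm.
#'
#' @export
setClass("TensorFieldPhantom",
  representation(
    fa = "array",
    directions = "array",
    mask = "array",
    labels = "array",
    voxelSize = "numeric"
  )
)

setValidity("TensorFieldPhantom", function(object) {
  msg <- character()
  d <- dim(object@fa)
  if (length(d) != 3L) msg <- c(msg, "fa must be a 3-D array")
  if (!identical(dim(object@mask), d)) msg <- c(msg, "mask dim mismatch")
  if (!identical(dim(object@labels), d)) msg <- c(msg, "labels dim mismatch")
  if (!identical(dim(object@directions), c(d, 3L)))
    msg <- c(msg, "directions must be dim(fa) x 3")
  if (any(object@fa < 0 | object@fa > 1)) msg <- c(msg, "fa outside [0, 1]")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be non-negative")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a positive scalar")
  dm <- matrix(object@directions, ncol = 3L)
  nrm <- sqrt(rowSums(dm^2))
  inmask <- as.vector(object@mask) & as.vector(object@fa) > 0
  if (any(inmask & abs(nrm - 1) > 1e-6 & nrm > 0))
    msg <- c(msg, "non-zero directions must have unit norm inside the mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TensorFieldPhantom", function(object) {
  d <- dim(object@fa)
  cat(sprintf(
    "TensorFieldPhantom: %d x %d x %d voxels @ %.2f mm, %d masked, %d parcels\n",
    d[1], d[2], d[3], object@voxelSize, sum(object@mask),
    length(setdiff(unique(as.vector(object@labels)), 0L))
  ))
})

#' Tracking parameters for FACT-style streamline propagation
#'
#' @slot faStartThreshold FA above which a voxel seeds a streamline.
#' @slot faStopThreshold FA below which propagation stops.
#' @slot maxTurnAngle maximum turning angle in degrees between the principal
#'   directions of successive voxels.
#' @slot stepSize propagation step in mm (default half voxel size when built
#'   via \code{trackingParams}).
#' @slot maxSteps cap on steps per branch.
#' @slot bidirectional logical; track both ways from the seed.
#'
#' @export
setClass("TrackingParams",
  representation(
    faStartThreshold = "numeric",
    faStopThreshold = "numeric",
    maxTurnAngle = "numeric",
    stepSize = "numeric",
    maxSteps = "integer",
    bidirectional = "logical"
  )
)

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@faStartThreshold <= 0 || object@faStartThreshold >= 1)
    msg <- c(msg, "faStartThreshold must be in (0, 1)")
  if (object@faStopThreshold <= 0 || object@faStopThreshold >= 1)
    msg <- c(msg, "faStopThreshold must be in (0, 1)")
  if (object@maxTurnAngle <= 0 || object@maxTurnAngle > 180)
    msg <- c(msg, "maxTurnAngle must be in (0, 180]")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be positive")
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct tracking parameters
#'
#' @param faStartThreshold seed threshold on FA (default 0.2).
#' @param faStopThreshold stop threshold on FA (default 0.2).
#' @param maxTurnAngle maximum turning angle in degrees (default 60).
#' @param stepSize step length in mm; default half of \code{voxelSize}.
#' @param maxSteps maximum steps per branch (default 2000).
#' @param bidirectional track in both directions from the seed (default TRUE).
#' @param voxelSize voxel size used to default \code{stepSize}.
#' @return A \code{TrackingParams} object.
#' @export
trackingParams <- function(faStartThreshold = 0.2, faStopThreshold = 0.2,
                           maxTurnAngle = 60, stepSize = NULL,
                           maxSteps = 2000L, bidirectional = TRUE,
                           voxelSize = 2.5) {
  if (is.null(stepSize)) stepSize <- voxelSize / 2
  new("TrackingParams",
    faStartThreshold = faStartThreshold, faStopThreshold = faStopThreshold,
    maxTurnAngle = maxTurnAngle, stepSize = stepSize,
    maxSteps = as.integer(maxSteps), bidirectional = bidirectional
  )
}

#' Set of reconstructed streamlines
#'
#' Each streamline is a list with elements \code{points} (an n x 3 matrix of
#' positions in mm, n >= 2) and \code{meanFA} (mean FA over the distinct
#' voxels traversed).
#'
#' @slot streamlines list of streamline records.
#' @slot sourceId provenance tag naming the phantom or subject of origin.
#'
#' @export
setClass("StreamlineSet",
  representation(streamlines = "list", sourceId = "character")
)

setValidity("StreamlineSet", function(object) {
  msg <- character()
  if (!nzchar(object@sourceId)) msg <- c(msg, "sourceId must be non-empty")
  for (s in object@streamlines) {
    if (!is.matrix(s$points) || ncol(s$points) != 3L || nrow(s$points) < 2L) {
      msg <- c(msg, "each streamline needs an n x 3 point matrix with n >= 2")
      break
    }
    if (s$meanFA < 0 || s$meanFA > 1) {
      msg <- c(msg, "meanFA must be in [0, 1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StreamlineSet", function(object) {
  np <- vapply(object@streamlines, function(s) nrow(s$points), integer(1))
  cat(sprintf(
    "StreamlineSet '%s': %d streamlines, median length %s points\n",
    object@sourceId, length(object@streamlines),
    if (length(np)) stats::median(np) else "NA"
  ))
})

#' Volumetric parcellation
#'
#' @slot labels integer 3-D array of parcel ids (0 = background).
#' @slot regionVolumes numeric vector of region volumes in mm^3, one per
#'   region id 1..R.
#' @slot regionNames character vector of region names.
#' @slot voxelSize voxel edge length in mm.
#'
#' @export
setClass("Parcellation",
  representation(
    labels = "array",
    regionVolumes = "numeric",
    regionNames = "character",
    voxelSize = "numeric"
  )
)

setValidity("Parcellation", function(object) {
  msg <- character()
  R <- length(object@regionVolumes)
  if (length(object@regionNames) != R)
    msg <- c(msg, "regionNames and regionVolumes lengths differ")
  if (max(object@labels) > R) msg <- c(msg, "labels exceed declared regions")
  present <- sort(setdiff(unique(as.vector(object@labels)), 0L))
  if (any(object@regionVolumes[present] <= 0))
    msg <- c(msg, "regions present in labels must have positive volume")
  if (length(msg)) msg else TRUE
})

#' Weighted structural connectome
#'
#' An undirected weighted network over R brain regions: a symmetric
#' non-negative R x R weight matrix with zero diagonal, the node (region)
#' volumes used for normalization, and the streamline count matrix retained
#' for provenance.
#'
#' @slot weights symmetric non-negative numeric matrix, zero diagonal.
#' @slot nodeVolumes region volumes in mm^3.
#' @slot streamlineCounts symmetric integer matrix of connecting streamline
#'   counts.
#'
#' @export
setClass("Connectome",
  representation(
    weights = "matrix",
    nodeVolumes = "numeric",
    streamlineCounts = "matrix"
  )
)

setValidity("Connectome", function(object) {
  msg <- character()
  W <- object@weights
  if (nrow(W) != ncol(W)) msg <- c(msg, "weights must be square")
  if (any(abs(W - t(W)) > 1e-12)) msg <- c(msg, "weights must be symmetric")
  if (any(diag(W) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(W < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@nodeVolumes) != nrow(W))
    msg <- c(msg, "nodeVolumes length must match matrix order")
  C <- object@streamlineCounts
  if (!identical(dim(C), dim(W))) msg <- c(msg, "streamlineCounts dim mismatch")
  if (any(C < 0) || any(abs(C - t(C)) > 0))
    msg <- c(msg, "streamlineCounts must be symmetric and non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Connectome", function(object) {
  W <- object@weights
  ne <- sum(W[upper.tri(W)] > 0)
  cat(sprintf(
    "Connectome: %d nodes, %d edges, density %.3f, mean weight %.4g\n",
    nrow(W), ne, 2 * ne / (nrow(W) * (nrow(W) - 1)),
    if (ne) mean(W[upper.tri(W)][W[upper.tri(W)] > 0]) else 0
  ))
})

#' Binary connectome
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal.
#'
#' @export
setClass("BinaryConnectome", representation(adjacency = "matrix"))

setValidity("BinaryConnectome", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
  if (any(A != t(A))) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinaryConnectome", function(object) {
  A <- object@adjacency
  cat(sprintf(
    "BinaryConnectome: %d nodes, %d edges\n", nrow(A), sum(A) / 2
  ))
})

#' Degree-preserving null ensemble summary
#'
#' Summaries of weighted global and local efficiency over Maslov–Sneppen
#' rewired null networks carrying the observed weight multiset.
#'
#' @slot nNulls number of null networks.
#' @slot swapsPerEdge attempted edge swaps per edge.
#' @slot seed RNG seed used.
#' @slot globalEff weighted global efficiency of each null.
#' @slot localEff weighted local efficiency of each null.
#'
#' @export
setClass("NullEnsemble",
  representation(
    nNulls = "integer",
    swapsPerEdge = "integer",
    seed = "integer",
    globalEff = "numeric",
    localEff = "numeric"
  )
)

setValidity("NullEnsemble", function(object) {
  msg <- character()
  if (length(object@globalEff) != object@nNulls ||
      length(object@localEff) != object@nNulls)
    msg <- c(msg, "per-null summaries must have length nNulls")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf(
    "NullEnsemble: %d nulls (%d swaps/edge, seed %d); mean Eglob %.4g, mean Eloc %.4g\n",
    object@nNulls, object@swapsPerEdge, object@seed,
    mean(object@globalEff), mean(object@localEff)
  ))
})

#' Simulation configuration for the synthetic cohort generator
#'
#' Holds every parameter of the data-generating process: cohort design
#' (sample size, visit times, per-visit retention), small-world connectome
#' topology and weights, the lesioning mechanism tied to a per-subject latent
#' severity, covariate links, and the longitudinal outcome model with subject
#' random intercept and slope. See \code{\link{simulationConfig}} for defaults
#' and units.
#'
#' @slot nSubjects number of subjects at baseline.
#' @slot visitTimes visit times in years, strictly increasing, first 0.
#' @slot nRetained subjects retained at each visit (non-increasing).
#' @slot nNodes connectome nodes.
#' @slot baseDegree even mean degree of the ring lattice before rewiring.
#' @slot rewireProb Watts–Strogatz rewiring probability.
#' @slot weightMeanlog,weightSdlog log-normal edge-weight parameters.
#' @slot severityShape1,severityShape2 Beta parameters of latent severity.
#' @slot edgeDeletionScale per-edge deletion probability is
#'   \code{edgeDeletionScale * severity}.
#' @slot weightAttenuationScale surviving weights are multiplied by
#'   \code{1 - weightAttenuationScale * severity}.
#' @slot fixedEffects named coefficients of the outcome model (z-units):
#'   intercept, covariate effects, \code{efficiency} (main effect of the
#'   standardized network predictor), \code{time} (slope per year).
#' @slot interactionBeta named per-outcome efficiency-by-time coefficients
#'   (z-units/year per SD of the predictor) for ci, pms, memory, aef.
#' @slot randomEffectsCov 2 x 2 covariance of (intercept, slope).
#' @slot residSd residual SD in z-units.
#' @slot attritionMode "severity" (rank-based informative dropout) or
#'   "random".
#' @slot efficiencyMeasure network measure driving the outcome model.
#' @slot seed base RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    visitTimes = "numeric",
    nRetained = "integer",
    nNodes = "integer",
    baseDegree = "integer",
    rewireProb = "numeric",
    weightMeanlog = "numeric",
    weightSdlog = "numeric",
    severityShape1 = "numeric",
    severityShape2 = "numeric",
    edgeDeletionScale = "numeric",
    weightAttenuationScale = "numeric",
    fixedEffects = "numeric",
    interactionBeta = "numeric",
    randomEffectsCov = "matrix",
    residSd = "numeric",
    attritionMode = "character",
    efficiencyMeasure = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(diff(object@visitTimes) <= 0))
    msg <- c(msg, "visitTimes must be strictly increasing")
  if (length(object@nRetained) != length(object@visitTimes))
    msg <- c(msg, "nRetained must match visitTimes length")
  if (any(diff(object@nRetained) > 0))
    msg <- c(msg, "nRetained must be non-increasing")
  if (any(object@nRetained > object@nSubjects))
    msg <- c(msg, "nRetained cannot exceed nSubjects")
  if (object@baseDegree < 2L) msg <- c(msg, "baseDegree must be >= 2")
  if (object@baseDegree %% 2L != 0L) msg <- c(msg, "baseDegree must be even")
  if (object@rewireProb < 0 || object@rewireProb > 1)
    msg <- c(msg, "rewireProb must be in [0, 1]")
  if (object@edgeDeletionScale < 0 || object@edgeDeletionScale > 1)
    msg <- c(msg, "edgeDeletionScale must be in [0, 1]")
  if (object@weightAttenuationScale < 0 || object@weightAttenuationScale > 1)
    msg <- c(msg, "weightAttenuationScale must be in [0, 1]")
  V <- object@randomEffectsCov
  if (!identical(dim(V), c(2L, 2L)) || any(abs(V - t(V)) > 1e-12))
    msg <- c(msg, "randomEffectsCov must be symmetric 2 x 2")
  if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    msg <- c(msg, "randomEffectsCov must be positive semi-definite")
  if (object@residSd < 0) msg <- c(msg, "residSd must be >= 0")
  if (!object@attritionMode %in% c("severity", "random"))
    msg <- c(msg, "attritionMode must be 'severity' or 'random'")
  need <- c("ci", "pms", "memory", "aef")
  if (!all(need %in% names(object@interactionBeta)))
    msg <- c(msg, "interactionBeta needs entries ci, pms, memory, aef")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0(
      "SimulationConfig: %d subjects, visits %s y (retained %s)\n",
      "  connectome: %d nodes, degree %d, rewire %.2f; severity Beta(%.3g, %.3g)\n",
      "  lesion: p_del = %.2f*s, attenuation 1 - %.2f*s; predictor %s\n",
      "  interaction betas: %s; seed %d\n"
    ),
    object@nSubjects, paste(object@visitTimes, collapse = "/"),
    paste(object@nRetained, collapse = "/"),
    object@nNodes, object@baseDegree, object@rewireProb,
    object@severityShape1, object@severityShape2,
    object@edgeDeletionScale, object@weightAttenuationScale,
    object@efficiencyMeasure,
    paste(sprintf("%s=%.3g", names(object@interactionBeta),
                  object@interactionBeta), collapse = ", "),
    object@seed
  ))
})
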