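#' Construct a tubular bundle phantom
#'
#' Builds a tensor-field phantom containing a straight or bent high-FA fiber
#' bundle with coherent principal directions, embedded in a low-FA
#' background. The two ends of the bundle are labelled as parcels 1 and 2 so
#' that end-to-end streamlines can be checked against the parcellation. The
#' bend, when requested, is a single elbow at the bundle midpoint, in the
#' plane spanned by the bundle axis and the next axis.
#'
#' @param shape integer vector of 3 grid dimensions.
#' @param bundleAxis axis (1, 2 or 3) of the first bundle segment.
#' @param bendAngle elbow angle in degrees (0 = straight).
#' @param faInside FA assigned to bundle voxels; must exceed 0.2 so that the
#'   bundle seeds streamlines under default thresholds.
#' @param faOutside FA of background voxels; must be below 0.2.
#' @param voxelSize voxel edge length in mm (default 2.5).
#' @param capDepth number of voxels at each end labelled as a parcel
#'   (default 2).
#' @return A \code{\linkS4class{TensorFieldPhantom}} with an all-true mask.
#' @examples
#' ph <- makeBundlePhantom(c(10, 10, 10))
#' sum(faVolume(ph) > 0.2)
#' @export
makeBundlePhantom <- function(shape, bundleAxis = 1L, bendAngle = 0,
                              faInside = 0.5, faOutside = 0,
                              voxelSize = 2.5, capDepth = 2L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("shape must have length 3")
  if (shape[bundleAxis] < 5L)
    stop("grid must be at least 5 voxels along the bundle axis")
  if (!(faInside > 0.2 && faOutside < 0.2))
    stop("need faInside > 0.2 > faOutside so tracking thresholds bite")

  # Work in a frame where the bundle runs along axis 1, permute back at the
  # end.
  perm <- switch(bundleAxis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  dimp <- shape[perm]
  n1 <- dimp[1]
  j0 <- ceiling(dimp[2] / 2)
  k0 <- ceiling(dimp[3] / 2)

  theta <- bendAngle * pi / 180
  d1 <- c(1, 0, 0)
  d2 <- c(cos(theta), sin(theta), 0)

  path <- list()
  dirs <- list()
  if (bendAngle == 0) {
    for (i in seq_len(n1)) {
      path[[length(path) + 1L]] <- c(i, j0, k0)
      dirs[[length(dirs) + 1L]] <- d1
    }
  } else {
    mid <- ceiling(n1 / 2)
    for (i in seq_len(mid - 1L)) {
      path[[length(path) + 1L]] <- c(i, j0, k0)
      dirs[[length(dirs) + 1L]] <- d1
    }
    # elbow voxel and second segment carry the rotated direction
    pos <- c(mid, j0, k0)
    path[[length(path) + 1L]] <- pos
    dirs[[length(dirs) + 1L]] <- d2
    t <- 0
    repeat {
      t <- t + 0.5
      v <- round(c(mid, j0, k0) + t * d2)
      if (any(v < 1L) || any(v > dimp)) break
      if (!identical(v, path[[length(path)]])) {
        path[[length(path) + 1L]] <- v
        dirs[[length(dirs) + 1L]] <- d2
      }
    }
  }

  fa <- array(faOutside, dim = dimp)
  labels <- array(0L, dim = dimp)
  directions <- array(0, dim = c(dimp, 3L))
  np <- length(path)
  capDepth <- min(as.integer(capDepth), floor(np / 2))
  for (q in seq_len(np)) {
    v <- path[[q]]
    fa[v[1], v[2], v[3]] <- faInside
    directions[v[1], v[2], v[3], ] <- dirs[[q]]
    if (q <= capDepth) labels[v[1], v[2], v[3]] <- 1L
    if (q > np - capDepth) labels[v[1], v[2], v[3]] <- 2L
  }

  iperm <- order(perm)
  new("TensorFieldPhantom",
    fa = aperm(fa, iperm),
    directions = aperm(directions, c(iperm, 4L)),
    mask = array(TRUE, dim = shape),
    labels = aperm(labels, iperm),
    voxelSize = voxelSize
  )
}

#' Write a phantom as a set of NIfTI volumes
#'
#' Writes six NIfTI files under \code{prefix}: \code{_fa}, \code{_dx},
#' \code{_dy}, \code{_dz}, \code{_mask} and \code{_labels}. Geometry is a
#' pure scaling by the voxel size.
#'
#' @param phantom a \code{TensorFieldPhantom}.
#' @param prefix output path prefix (directory must exist).
#' @return Invisibly, the vector of file paths written.
#' @export
writePhantom <- function(phantom, prefix) {
  stopifnot(is(phantom, "TensorFieldPhantom"))
  vs <- rep(phantom@voxelSize, 3)
  comps <- list(
    fa = phantom@fa,
    dx = phantom@directions[, , , 1],
    dy = phantom@directions[, , , 2],
    dz = phantom@directions[, , , 3],
    mask = array(as.numeric(phantom@mask), dim = dim(phantom@mask)),
    labels = array(as.numeric(phantom@labels), dim = dim(phantom@labels))
  )
  paths <- character(0)
  for (nm in names(comps)) {
    img <- RNifti::asNifti(comps[[nm]])
    RNifti::pixdim(img) <- vs
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a phantom written by \code{writePhantom}
#'
#' @param prefix path prefix used when writing.
#' @return A \code{TensorFieldPhantom}.
#' @export
readPhantom <- function(prefix) {
  rd <- function(nm) {
    img <- RNifti::readNifti(paste0(prefix, "_", nm, ".nii.gz"))
    array(as.numeric(img), dim = dim(img))
  }
  fa <- rd("fa")
  d <- dim(fa)
  directions <- array(0, dim = c(d, 3L))
  directions[, , , 1] <- rd("dx")
  directions[, , , 2] <- rd("dy")
  directions[, , , 3] <- rd("dz")
  vs <- RNifti::pixdim(RNifti::readNifti(paste0(prefix, "_fa.nii.gz")))[1]
  new("TensorFieldPhantom",
    fa = fa, directions = directions,
    mask = array(rd("mask") > 0.5, dim = d),
    labels = array(as.integer(round(rd("labels"))), dim = d),
    voxelSize = vs
  )
}
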