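#' Construct a LabelVolume
#'
#' @param labels 3D array of non-negative integer labels.
#' @param affine 4x4 voxel-to-world matrix (RAS mm); voxel indices are
#'   0-based when mapped through the affine.
#' @param spaceId name of the coordinate space.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, affine = diag(4), spaceId = "subject") {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, affine = affine, spaceId = spaceId)
}

#' Create an empty reference grid
#'
#' Convenience constructor for the common reference space into which
#' individual delineations are resampled before computing probability maps.
#' The default is a 1 mm isotropic grid, the resolution at which probabilistic
#' cytoarchitectonic maps are conventionally published.
#'
#' @param dim integer triplet, grid dimensions.
#' @param origin world coordinate (mm) of the centre of voxel (0,0,0).
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param spaceId name of the reference space.
#' @return A \linkS4class{LabelVolume} of zeros.
#' @export
referenceGrid <- function(dim = c(80L, 50L, 40L), origin = c(-40, -45, -25),
                          voxelSize = 1, spaceId = "reference") {
  voxelSize <- rep_len(voxelSize, 3L)
  aff <- diag(c(voxelSize, 1))
  aff[1:3, 4] <- origin
  LabelVolume(array(0L, dim), aff, spaceId)
}

## voxel (0-based, n x 3) -> world (n x 3)
voxelToWorld <- function(affine, idx) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

## world (n x 3) -> voxel (0-based, n x 3, unrounded)
worldToVoxel <- function(affine, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE]
}

## world coordinates of every voxel centre along one grid axis
axisWorldCoords <- function(volume, axis) {
  d <- dim(volume@labels)
  idx <- matrix(0, d[axis], 3)
  idx[, axis] <- seq_len(d[axis]) - 1
  voxelToWorld(volume@affine, idx)[, axis]
}

#' Read or write a LabelVolume as NIfTI-1
#'
#' Label volumes are stored as int16 NIfTI-1 images with the voxel-to-world
#' affine in the sform (code 2).  `readLabelVolume` restores the 0-based
#' voxel-index convention used throughout the package.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spaceId space identifier to attach on read.
#' @return `readLabelVolume` returns a \linkS4class{LabelVolume};
#'   `writeLabelVolume` returns `path` invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@labels, datatype = "int16")
  RNifti::sform(img) <- structure(volume@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path, spaceId = "subject") {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- array(as.integer(img), dim = dim(img))
  LabelVolume(arr, aff, spaceId)
}

#' Split a label volume at the midsagittal plane
#'
#' The midline is the world x = 0 plane: voxels whose centre has x < 0 belong
#' to the left hemisphere, x > 0 to the right (RAS convention).
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param hemisphere `"left"` or `"right"`.
#' @return A \linkS4class{LabelVolume} with labels outside the requested
#'   hemisphere set to 0.
#' @export
hemisphereVolume <- function(volume, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  d <- dim(volume@labels)
  ## world x of voxel centres depends only on the voxel index through the
  ## affine; evaluate on the full index grid
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  A <- volume@affine
  wx <- outer(outer(A[1, 1] * i, A[1, 2] * j, `+`), A[1, 3] * k, `+`) + A[1, 4]
  keep <- if (hemisphere == "left") wx < 0 else wx > 0
  labs <- volume@labels
  labs[!keep] <- 0L
  LabelVolume(labs, volume@affine, volume@spaceId)
}
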