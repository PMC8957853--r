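## signed distance transform of a binary mask, pixel units, positive inside
signedDistance <- function(mask) {
  if (!any(mask)) return(matrix(-1e6, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(1e6, nrow(mask), ncol(mask)))
  m <- mask * 1
  EBImage::distmap(m) - EBImage::distmap(1 - m)
}

#' Reconstruct a 3D label volume from a sparse section stack
#'
#' Fills the gaps between systematically sampled sections either by block
#' extrusion (each sampled mask fills the slab it represents, up to the next
#' sampled section) or by shape-based interpolation: between consecutive
#' sampled sections the structure boundary is interpolated by linearly
#' blending the two signed distance transforms and thresholding at zero.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param interpolation `"block"` or `"shape_based"`.
#' @param axisPitch voxel pitch of the reconstructed grid along the slicing
#'   axis, mm; must not exceed the inter-section distance.
#' @return A binary \linkS4class{LabelVolume} (label 1 inside) on a grid with
#'   the stack's in-plane geometry and `axisPitch` spacing along the axis.
#' @export
stackToVolume <- function(stack, interpolation = c("block", "shape_based"),
                          axisPitch = 0.1) {
  stopifnot(is(stack, "SectionStack"))
  interpolation <- match.arg(interpolation)
  d <- sectionSpacing(stack)
  if (axisPitch <= 0 || axisPitch > d)
    stop("axisPitch must lie in (0, inter-section distance]")
  nsec <- nSections(stack)
  if (nsec == 0L) stop("empty stack")
  if (nsec == 1L && interpolation == "shape_based") {
    warning("single-section stack: falling back to block interpolation")
    interpolation <- "block"
  }
  axis <- stack@axis
  srcA <- stack@sourceAffine
  pitchSrc <- abs(srcA[axis, axis])
  blockLen <- stack@sourceDim[axis] * pitchSrc
  b0 <- srcA[axis, 4] - pitchSrc / 2          # world start of the block
  nL <- max(1L, floor(blockLen / axisPitch))
  yl <- b0 + (seq_len(nL) - 0.5) * axisPitch  # output layer centres
  planes <- b0 + stack@sectionIndex * stack@thickness

  mdim <- dim(stack@sections[[1]])
  out <- array(0L, c(mdim[1], nL, mdim[2]))   # assembled with axis second,
                                              # permuted at the end if needed
  sdts <- NULL
  if (interpolation == "shape_based") {
    sdts <- lapply(stack@sections, signedDistance)
    ## a structure ending between two sections tapers out: an empty
    ## neighbour acts as a uniform negative plateau at the depth of the
    ## non-empty mask's centre, so the interpolated boundary shrinks to
    ## extinction across the gap instead of being cut off at the last
    ## sampled section
    for (m in seq_len(nsec - 1L)) {
      e1 <- !any(stack@sections[[m]]); e2 <- !any(stack@sections[[m + 1L]])
      if (e1 && !e2)
        sdts[[m]] <- matrix(-max(sdts[[m + 1L]]), nrow(sdts[[m]]),
                            ncol(sdts[[m]]))
      else if (e2 && !e1)
        sdts[[m + 1L]] <- matrix(-max(sdts[[m]]), nrow(sdts[[m]]),
                                 ncol(sdts[[m]]))
    }
  }

  idx <- findInterval(yl, planes)             # 0 = before the first plane
  for (l in seq_len(nL)) {
    m <- idx[l]
    if (m == 0L) next
    if (interpolation == "block" || m == nsec) {
      mask <- stack@sections[[m]]
    } else {
      t <- (yl[l] - planes[m]) / (planes[m + 1] - planes[m])
      sd <- (1 - t) * sdts[[m]] + t * sdts[[m + 1]]
      mask <- sd > 0
    }
    if (any(mask)) out[, l, ][mask] <- 1L
  }

  ## build the output affine: in-plane geometry inherited from the source,
  ## axisPitch spacing along the slicing axis
  perm <- switch(axis, c(2L, 1L, 3L), c(1L, 2L, 3L), c(1L, 3L, 2L))
  out <- aperm(out, order(perm))
  inPlaneAxes <- (1:3)[-axis]
  aff <- diag(4)
  aff[inPlaneAxes[1], inPlaneAxes[1]] <- srcA[inPlaneAxes[1], inPlaneAxes[1]]
  aff[inPlaneAxes[2], inPlaneAxes[2]] <- srcA[inPlaneAxes[2], inPlaneAxes[2]]
  aff[axis, axis] <- axisPitch
  aff[inPlaneAxes, 4] <- srcA[inPlaneAxes, 4]
  aff[axis, 4] <- b0 + axisPitch / 2
  LabelVolume(out, aff, spaceId = stack@subjectId)
}

#' Resample a structure into a reference grid
#'
#' Nearest-neighbour pull-back resampling: every reference voxel centre is
#' mapped through the inverse of the subject-to-reference transform into the
#' subject grid and the nearest subject voxel is read.  Labels are never
#' blended.
#'
#' @param volume subject \linkS4class{LabelVolume}.
#' @param transform 4x4 affine mapping subject world mm to reference world mm
#'   (invertible).
#' @param reference a \linkS4class{LabelVolume} defining the reference grid
#'   (see \code{\link{referenceGrid}}).
#' @param label integer label(s) selecting the structure; the output is a
#'   binary mask of voxels whose pulled-back label is in `label`.
#' @return Binary \linkS4class{LabelVolume} on the reference grid.
#' @export
toReference <- function(volume, transform, reference, label) {
  stopifnot(is(volume, "LabelVolume"), is(reference, "LabelVolume"))
  if (abs(det(transform)) < .Machine$double.eps)
    stop("transform must be invertible")
  M <- solve(volume@affine) %*% solve(transform) %*% reference@affine
  dref <- dim(reference@labels)
  idx <- as.matrix(expand.grid(i = 0:(dref[1] - 1), j = 0:(dref[2] - 1),
                               k = 0:(dref[3] - 1)))
  sub <- idx %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(idx), 3, byrow = TRUE)
  sub <- round(sub)
  dsub <- dim(volume@labels)
  ok <- sub[, 1] >= 0 & sub[, 1] < dsub[1] &
        sub[, 2] >= 0 & sub[, 2] < dsub[2] &
        sub[, 3] >= 0 & sub[, 3] < dsub[3]
  vals <- integer(nrow(idx))
  lin <- sub[ok, 1] + dsub[1] * (sub[ok, 2] + dsub[2] * sub[ok, 3]) + 1
  vals[ok] <- volume@labels[lin]
  mask <- array(as.integer(vals %in% label), dref)
  if (!any(mask > 0))
    stop("structure maps entirely outside the reference grid")
  LabelVolume(mask, reference@affine, reference@spaceId)
}

#' Superimpose subject masks into a probability map
#'
#' The overlap percentage of a voxel is 100 times the fraction of subjects
#' whose mask contains it: with ten subjects, a voxel covered by exactly one
#' subject scores 10\%, a voxel covered by all ten scores 100\%.  Exact
#' fractions are stored; \code{\link{percentMap}} rounds them to integers
#' for export.
#'
#' @param masks list of binary \linkS4class{LabelVolume}s on one common grid.
#' @param structure structure name for the map.
#' @return A \linkS4class{ProbabilityMap}.
#' @export
computeProbabilityMap <- function(masks, structure = "structure") {
  if (length(masks) < 1L) stop("need at least one mask")
  ref <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m@labels), dim(ref@labels)) ||
        max(abs(m@affine - ref@affine)) > 1e-8 ||
        !identical(m@spaceId, ref@spaceId))
      stop("all masks must share the same grid and space")
  }
  n <- length(masks)
  count <- Reduce(`+`, lapply(masks, function(m) (m@labels > 0) * 1))
  new("ProbabilityMap", structure = structure,
      percent = count * (100 / n), nSubjects = as.integer(n),
      affine = ref@affine, spaceId = ref@spaceId)
}

#' Extract the percent grid of a probability map
#'
#' @param map a \linkS4class{ProbabilityMap}.
#' @param rounded round to integer percentages (the published convention for
#'   ten subjects: steps of 10)?
#' @return 3D numeric (or integer) array of overlap percentages.
#' @export
percentMap <- function(map, rounded = TRUE) {
  stopifnot(is(map, "ProbabilityMap"))
  if (rounded) {
    p <- round(map@percent)
    storage.mode(p) <- "integer"
    p
  } else map@percent
}

#' Centre of mass of a probability map
#'
#' Probability-weighted mean of the world coordinates of the map's voxels,
#' optionally restricted to one hemisphere (midline at world x = 0), rounded
#' to the nearest integer mm as conventionally reported.
#'
#' @param map a \linkS4class{ProbabilityMap}.
#' @param hemisphere `"both"`, `"left"` or `"right"`.
#' @param weighted if `FALSE`, all covered voxels weigh equally.
#' @param rounded round to integer mm?
#' @return Named numeric vector `c(x, y, z)` in reference mm.
#' @export
centerOfMass <- function(map, hemisphere = c("both", "left", "right"),
                         weighted = TRUE, rounded = TRUE) {
  stopifnot(is(map, "ProbabilityMap"))
  hemisphere <- match.arg(hemisphere)
  nz <- which(map@percent > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("empty probability map")
  w <- map@percent[nz]
  xyz <- voxelToWorld(map@affine, nz - 1)
  keep <- switch(hemisphere, both = rep(TRUE, nrow(xyz)),
                 left = xyz[, 1] < 0, right = xyz[, 1] > 0)
  if (!any(keep)) stop("no map voxels in the requested hemisphere")
  xyz <- xyz[keep, , drop = FALSE]
  w <- if (weighted) w[keep] else rep(1, sum(keep))
  com <- colSums(xyz * w) / sum(w)
  if (rounded) com <- round(com)
  stats::setNames(com, c("x", "y", "z"))
}

#' Threshold a probability map
#'
#' @param map a \linkS4class{ProbabilityMap}.
#' @param tPercent threshold in percent, 0 <= t <= 100; `t = 0` selects all
#'   voxels with any overlap, `t = 100` the intersection of all subjects.
#' @return Binary \linkS4class{LabelVolume} on the map's grid.
#' @export
thresholdMap <- function(map, tPercent) {
  stopifnot(is(map, "ProbabilityMap"))
  if (tPercent < 0 || tPercent > 100) stop("tPercent must be in [0, 100]")
  mask <- if (tPercent == 0) map@percent > 0 else map@percent >= tPercent
  LabelVolume(array(as.integer(mask), dim(map@percent)), map@affine,
              map@spaceId)
}

#' Write a probability map as NIfTI-1
#'
#' Stored as uint8 integer percentages with the reference affine in the
#' sform.
#'
#' @param map a \linkS4class{ProbabilityMap}.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeProbabilityMap <- function(map, path) {
  img <- RNifti::asNifti(percentMap(map), datatype = "uint8")
  RNifti::sform(img) <- structure(map@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
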