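#' Serially section a label volume
#'
#' Emulates serial coronal sectioning at thickness `thickness` (mm) with
#' systematic sampling of every `interval`-th section, as in classical
#' stereological practice (20 um sections, every 15th kept, giving an
#' inter-section distance of 300 um).  Sections are modelled as
#' infinitesimally thin planes at the section's front face; each sampled
#' plane is rasterized by reading the voxel layer that contains it.  Planes
#' within the tissue block but outside the structure yield empty masks that
#' are retained with zero area.
#'
#' @param volume a \linkS4class{LabelVolume} with an axis-aligned affine.
#' @param structure label id (integer) or structure name when `labelMap` is
#'   given.
#' @param thickness section thickness T in mm (default 0.020).
#' @param interval sampling interval k (default 15).
#' @param offset index of the first sampled section in `[0, interval)`; if
#'   `NULL`, drawn uniformly (the sampling lattice of a real sectioning run
#'   starts at an arbitrary phase).
#' @param axis slicing axis in the voxel grid (default 2, the
#'   anterior-posterior axis of an RAS grid: coronal planes).
#' @param labelMap optional named integer vector mapping structure names to
#'   labels, e.g. `c(MGBv = 1)`.
#' @param subjectId subject identifier stored in the stack.
#' @return A \linkS4class{SectionStack}.
#' @export
sliceVolume <- function(volume, structure, thickness = 0.020, interval = 15L,
                        offset = NULL, axis = 2L, labelMap = NULL,
                        subjectId = "subject") {
  stopifnot(is(volume, "LabelVolume"))
  if (thickness <= 0) stop("thickness must be > 0")
  interval <- as.integer(interval)
  if (interval < 1L) stop("interval must be >= 1")
  A <- volume@affine
  if (any(abs(A[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))]) > 1e-9))
    stop("sectioning requires an axis-aligned (diagonal-affine) volume")
  label <- structure
  sname <- as.character(structure)
  if (is.character(structure)) {
    if (is.null(labelMap) || !structure %in% names(labelMap))
      stop("structure name requires a labelMap entry")
    label <- labelMap[[structure]]
  }
  if (!any(volume@labels == label))
    stop("structure label ", label, " absent from volume")
  if (is.null(offset)) offset <- sample.int(interval, 1L) - 1L
  offset <- as.integer(offset)
  if (offset < 0L || offset >= interval)
    stop("offset must satisfy 0 <= offset < interval")

  d <- dim(volume@labels)
  pitch <- abs(A[axis, axis])
  blockLen <- d[axis] * pitch          # tissue extent along the slicing axis
  nSec <- floor(blockLen / thickness)  # complete sections in the block
  sampled <- seq.int(offset, nSec - 1L, by = interval)
  ## front-face plane of section s sits at distance s*T from the block start;
  ## it falls in voxel layer floor(s*T / pitch)
  layer <- pmin(floor(sampled * thickness / pitch), d[axis] - 1L) + 1L

  binary <- volume@labels == label
  masks <- lapply(layer, function(l) {
    switch(axis,
      `1` = binary[l, , ],
      `2` = binary[, l, ],
      `3` = binary[, , l])
  })
  inPlane <- abs(diag(A)[1:3][-axis])
  new("SectionStack", subjectId = subjectId, structure = sname,
      sections = masks, sectionIndex = as.integer(sampled),
      thickness = thickness, interval = interval, offset = offset,
      axis = as.integer(axis), pixelSize = inPlane,
      sourceAffine = A, sourceDim = as.integer(d))
}

#' Area of one section profile
#'
#' True-pixel count times pixel area.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param i section position within the stack (1-based).
#' @return Area in mm^2.
#' @seealso \code{\link{sectionAreas}} for all areas at once.
#' @export
sectionArea <- function(stack, i) {
  stopifnot(is(stack, "SectionStack"))
  if (i < 1L || i > nSections(stack)) stop("section index out of range")
  sum(stack@sections[[i]]) * prod(stack@pixelSize)
}
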