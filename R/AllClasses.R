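#' @import methods
NULL

#' LabelVolume: a 3D integer label grid in world coordinates
#'
#' A dense 3D array of non-negative integer labels together with a 4x4
#' voxel-to-world affine (RAS, mm).  Voxel indices are 0-based when mapped
#' through the affine: world = affine %*% c(i, j, k, 1) gives the centre of
#' the voxel stored at `labels[i+1, j+1, k+1]`.
#'
#' @slot labels 3D integer array of labels (0 = background).
#' @slot affine 4x4 voxel-to-world matrix (RAS, mm), invertible.
#' @slot spaceId character scalar naming the coordinate space.
#' @export
setClass("LabelVolume",
  representation(labels = "array", affine = "matrix", spaceId = "character"))

setValidity("LabelVolume", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be invertible")
  if (any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative")
  if (length(object@spaceId) != 1L)
    msg <- c(msg, "spaceId must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' SectionStack: sparse serial sections of one structure
#'
#' Ordered 2D binary masks obtained by cutting a \linkS4class{LabelVolume}
#' into serial sections of thickness `thickness` (mm) and keeping every
#' `interval`-th section, starting at section index `offset`.  Empty masks
#' inside the sampled range are retained (zero area).
#'
#' @slot subjectId character scalar.
#' @slot structure character scalar, the structure name.
#' @slot sections list of logical matrices, all of identical dimension.
#' @slot sectionIndex integer vector of sampled section indices (0-based,
#'   strictly increasing, consecutive entries differ by `interval`).
#' @slot thickness section thickness T in mm (e.g. 0.020).
#' @slot interval systematic sampling interval k (e.g. 15).
#' @slot offset index of the first sampled section, 0 <= offset < interval.
#' @slot axis slicing axis (1, 2 or 3 in the volume's voxel grid).
#' @slot pixelSize in-plane pixel size, mm, length 2.
#' @slot sourceAffine affine of the source volume (for reconstruction).
#' @slot sourceDim dimension of the source volume grid.
#' @export
setClass("SectionStack",
  representation(subjectId = "character", structure = "character",
    sections = "list", sectionIndex = "integer",
    thickness = "numeric", interval = "integer", offset = "integer",
    axis = "integer", pixelSize = "numeric",
    sourceAffine = "matrix", sourceDim = "integer"))

setValidity("SectionStack", function(object) {
  msg <- NULL
  n <- length(object@sections)
  if (length(object@sectionIndex) != n)
    msg <- c(msg, "sectionIndex length must match number of sections")
  if (n > 1L) {
    d <- diff(object@sectionIndex)
    if (any(d <= 0L)) msg <- c(msg, "sectionIndex must be strictly increasing")
    if (any(d != object@interval))
      msg <- c(msg, "consecutive sampled indices must differ by `interval`")
    dims <- vapply(object@sections, function(m) paste(dim(m), collapse = "x"),
                   character(1))
    if (length(unique(dims)) > 1L)
      msg <- c(msg, "all masks must share the same shape")
  }
  if (object@thickness <= 0) msg <- c(msg, "thickness must be > 0")
  if (object@interval < 1L) msg <- c(msg, "interval must be >= 1")
  if (object@offset < 0L || object@offset >= object@interval)
    msg <- c(msg, "offset must satisfy 0 <= offset < interval")
  if (!(object@axis %in% 1:3)) msg <- c(msg, "axis must be 1, 2 or 3")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be two positive numbers")
  if (is.null(msg)) TRUE else msg
})

#' ProbabilityMap: voxel-wise overlap across subjects
#'
#' Per-voxel percentage (0-100) of subjects whose delineation of a structure,
#' after transfer to a common reference grid, covers the voxel.  Exact
#' fractions are stored internally; \code{\link{percentMap}} returns them
#' rounded to integers as published.
#'
#' @slot structure character scalar.
#' @slot percent 3D numeric array of exact overlap percentages in [0, 100].
#' @slot nSubjects integer, number of superimposed subjects.
#' @slot affine 4x4 voxel-to-world matrix of the reference grid.
#' @slot spaceId reference space identifier.
#' @export
setClass("ProbabilityMap",
  representation(structure = "character", percent = "array",
    nSubjects = "integer", affine = "matrix", spaceId = "character"))

setValidity("ProbabilityMap", function(object) {
  msg <- NULL
  if (length(dim(object@percent)) != 3L)
    msg <- c(msg, "percent must be a 3D array")
  if (any(object@percent < 0 | object@percent > 100))
    msg <- c(msg, "percent values must lie in [0, 100]")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (is.null(msg)) TRUE else msg
})

#' SurfaceMesh: closed triangulated surface in mm
#'
#' @slot vertices numeric matrix, n x 3, world mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices, consistently
#'   oriented (outward normals).
#' @slot structure character scalar.
#' @slot spaceId character scalar.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
    structure = "character", spaceId = "character"))

setValidity("SurfaceMesh", function(object) {
  msg <- NULL
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  f <- object@faces
  if (nrow(f) > 0L && (min(f) < 1L || max(f) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (is.null(msg)) TRUE else msg
})
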