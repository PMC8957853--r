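#' Accessors for cytoatlas classes
#'
#' `labelArray`, `affineMatrix`, `voxelSize` and `spaceId` expose the slots of
#' \linkS4class{LabelVolume} and \linkS4class{ProbabilityMap} objects;
#' `nSections`, `sectionSpacing` and `sectionAreas` summarize a
#' \linkS4class{SectionStack}; `vertices` and `faces` expose a
#' \linkS4class{SurfaceMesh}.
#'
#' @param object a cytoatlas object.
#' @param ... further arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(object) standardGeneric("affineMatrix"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("spaceId", function(object) standardGeneric("spaceId"))

#' @rdname accessors
#' @export
setGeneric("nSections", function(object) standardGeneric("nSections"))

#' @rdname accessors
#' @export
setGeneric("sectionSpacing", function(object) standardGeneric("sectionSpacing"))

#' @rdname accessors
#' @export
setGeneric("sectionAreas", function(object) standardGeneric("sectionAreas"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))

#' @rdname accessors
#' @export
setMethod("labelArray", "LabelVolume", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("affineMatrix", "LabelVolume", function(object) object@affine)

#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelVolume",
  function(object) sqrt(colSums(object@affine[1:3, 1:3]^2)))

#' @rdname accessors
#' @export
setMethod("spaceId", "LabelVolume", function(object) object@spaceId)

#' @rdname accessors
#' @export
setMethod("affineMatrix", "ProbabilityMap", function(object) object@affine)

#' @rdname accessors
#' @export
setMethod("voxelSize", "ProbabilityMap",
  function(object) sqrt(colSums(object@affine[1:3, 1:3]^2)))

#' @rdname accessors
#' @export
setMethod("spaceId", "ProbabilityMap", function(object) object@spaceId)

#' @rdname accessors
#' @export
setMethod("nSections", "SectionStack", function(object) length(object@sections))

#' @rdname accessors
#' @export
setMethod("sectionSpacing", "SectionStack",
  function(object) object@interval * object@thickness)

#' @rdname accessors
#' @export
setMethod("sectionAreas", "SectionStack", function(object) {
  pa <- prod(object@pixelSize)
  vapply(object@sections, function(m) sum(m) * pa, numeric(1))
})

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(object) object@vertices)

#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(object) object@faces)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  cat("LabelVolume in space '", object@spaceId, "'\n", sep = "")
  cat("  grid: ", paste(d, collapse = " x "),
      " voxels at ", paste(signif(voxelSize(object), 3), collapse = " x "),
      " mm\n", sep = "")
  cat("  labels present: ",
      if (length(labs)) paste(labs, collapse = ", ") else "(none)", "\n",
      sep = "")
})

setMethod("show", "SectionStack", function(object) {
  cat("SectionStack: subject '", object@subjectId, "', structure '",
      object@structure, "'\n", sep = "")
  cat("  ", nSections(object), " sections (every ", object@interval,
      "th of ", object@thickness * 1000, " um; spacing ",
      sectionSpacing(object), " mm; offset ", object@offset, ")\n", sep = "")
  a <- sectionAreas(object)
  cat("  non-empty sections: ", sum(a > 0), "; total area ",
      signif(sum(a), 5), " mm^2\n", sep = "")
})

setMethod("show", "ProbabilityMap", function(object) {
  cat("ProbabilityMap for '", object@structure, "' over ", object@nSubjects,
      " subjects in space '", object@spaceId, "'\n", sep = "")
  cat("  grid: ", paste(dim(object@percent), collapse = " x "),
      " voxels; nonzero voxels: ", sum(object@percent > 0), "\n", sep = "")
})

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh for '", object@structure, "' in space '", object@spaceId,
      "'\n  ", nrow(object@vertices), " vertices, ", nrow(object@faces),
      " faces\n", sep = "")
})
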