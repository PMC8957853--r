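#' Cavalieri volume estimate from a section stack
#'
#' The classical stereological estimator V = d * sum(A_i) with d = k * T the
#' inter-section distance and A_i the profile areas of the systematically
#' sampled sections (empty sections contribute zero).
#'
#' @param stack a \linkS4class{SectionStack}.
#' @return Volume in mm^3.
#' @export
cavalieriVolume <- function(stack) {
  stopifnot(is(stack, "SectionStack"))
  if (nSections(stack) == 0L)
    stop("empty stack: no sections were sampled")
  sectionSpacing(stack) * sum(sectionAreas(stack))
}

#' Correct a measured volume for tissue shrinkage
#'
#' Histological processing (fixation, embedding) shrinks the tissue; a
#' volumetric shrinkage factor f >= 1 converts volumes measured in the
#' processed tissue back to fresh scale: V_corr = V_raw * f.
#'
#' @param vRaw measured (in-tissue) volume, mm^3.
#' @param f volumetric shrinkage factor, dimensionless, >= 1.
#' @return Corrected volume in mm^3.
#' @export
correctShrinkage <- function(vRaw, f) {
  if (any(f < 1)) stop("shrinkage factors inflate histological volumes: f >= 1")
  vRaw * f
}

#' Normalize a volume by total brain volume
#'
#' @param vCorr shrinkage-corrected structure volume, mm^3.
#' @param brainVolume total fresh brain volume, mm^3, > 0.
#' @return Dimensionless proportion vCorr / brainVolume.
#' @export
normalizeVolume <- function(vCorr, brainVolume) {
  if (any(brainVolume <= 0)) stop("brainVolume must be > 0")
  vCorr / brainVolume
}

#' Volume from voxel counts
#'
#' Number of structure voxels times the physical voxel volume, optionally
#' scaled by a shrinkage factor, as used for fully reconstructed label
#' volumes.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param structure integer label.
#' @param f volumetric shrinkage factor (default 1).
#' @return Volume in mm^3.
#' @export
voxelCountVolume <- function(volume, structure, f = 1) {
  stopifnot(is(volume, "LabelVolume"))
  M <- volume@affine[1:3, 1:3]
  ## the voxel volume element is only well-defined for shear-free affines
  G <- crossprod(M)
  if (any(abs(G[upper.tri(G)]) > 1e-9 * max(abs(diag(G)))))
    stop("affine has shear: voxel volume element ill-defined")
  n <- sum(volume@labels == structure)
  if (n == 0L) stop("structure label ", structure, " absent from volume")
  n * abs(det(M)) * f
}

#' Sum volume estimates across structures
#'
#' Component-wise sum of raw and corrected volumes over rows of a tidy
#' volume-estimate table, e.g. to add the subdivisions of a nucleus into a
#' "sum of subdivisions" estimate.  All rows must share subject, hemisphere
#' and method.
#'
#' @param estimates data.frame with columns `subject_id`, `structure`,
#'   `hemisphere`, `method`, `V_raw_mm3`, `V_corr_mm3` and optionally
#'   `proportion`.
#' @param structure name given to the summed estimate.
#' @return A one-row data.frame of the same shape.
#' @export
sumStructures <- function(estimates, structure = "sum") {
  if (nrow(estimates) == 0L) stop("no estimates to sum")
  if (length(unique(estimates$subject_id)) > 1L)
    stop("estimates span multiple subjects")
  if (length(unique(estimates$hemisphere)) > 1L)
    stop("estimates span multiple hemispheres")
  if (length(unique(estimates$method)) > 1L)
    stop("estimates span multiple methods")
  out <- estimates[1, , drop = FALSE]
  out$structure <- structure
  out$V_raw_mm3 <- sum(estimates$V_raw_mm3)
  out$V_corr_mm3 <- sum(estimates$V_corr_mm3)
  if ("proportion" %in% names(estimates))
    out$proportion <- sum(estimates$proportion)
  rownames(out) <- NULL
  out
}

#' Aggregate a volume table over grouping columns
#'
#' Sums `V_raw_mm3`, `V_corr_mm3` and (if present) `proportion` within groups,
#' e.g. `by = c("subject_id", "structure")` adds the two hemispheres into
#' bilateral volumes.
#'
#' @param estimates tidy volume table (see \code{\link{cohortVolumetry}}).
#' @param by character vector of grouping columns.
#' @return Aggregated data.frame.
#' @export
aggregateVolumes <- function(estimates, by) {
  cols <- intersect(c("V_raw_mm3", "V_corr_mm3", "proportion"),
                    names(estimates))
  stats::aggregate(estimates[cols], estimates[by], sum)
}

#' Stereological volumetry of a whole cohort
#'
#' For every subject, structure and hemisphere: restrict the subject's label
#' volume to the hemisphere (midline at world x = 0), section it
#' systematically, apply the Cavalieri estimator, correct for shrinkage and
#' normalize by brain volume.  With `method = "voxel_count"` the full voxel
#' grid is counted instead of sectioning.
#'
#' @param cohort result of \code{\link{generateCohort}} (with volumes).
#' @param thickness,interval sectioning parameters (mm, count).
#' @param offsets optional integer vector of per-subject section offsets; by
#'   default each subject's offset is drawn from its sectioning seed.
#' @param method `"cavalieri"` or `"voxel_count"`.
#' @param seed seed for the per-subject offset draws.
#' @return Tidy data.frame: subject_id, sex, structure, hemisphere, method,
#'   V_raw_mm3, V_corr_mm3, proportion.
#' @export
cohortVolumetry <- function(cohort, thickness = 0.020, interval = 15L,
                            offsets = NULL, method = c("cavalieri",
                            "voxel_count"), seed = 1L) {
  method <- match.arg(method)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  if (is.null(cohort$volumes)) stop("cohort has no label volumes")
  labMap <- structureLabels(cohort)
  if (is.null(offsets)) {
    set.seed(seed)
    offsets <- sample.int(interval, n, replace = TRUE) - 1L
  }
  rows <- list()
  for (i in seq_len(n)) {
    vol <- cohort$volumes[[i]]
    sid <- subjects$subject_id[i]
    f <- subjects$shrinkage_factor[i]
    bv <- subjects$brain_volume_mm3[i]
    for (h in c("left", "right")) {
      hv <- hemisphereVolume(vol, h)
      for (s in names(labMap)) {
        vRaw <- if (method == "cavalieri") {
          st <- sliceVolume(hv, labMap[[s]], thickness, interval,
                            offset = offsets[i], subjectId = sid)
          cavalieriVolume(st)
        } else {
          voxelCountVolume(hv, labMap[[s]])
        }
        rows[[length(rows) + 1L]] <- data.frame(subject_id = sid,
          sex = subjects$sex[i], structure = s, hemisphere = h,
          method = method, V_raw_mm3 = vRaw,
          V_corr_mm3 = correctShrinkage(vRaw, f),
          proportion = normalizeVolume(correctShrinkage(vRaw, f), bv),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Structure name to label mapping of a cohort
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @return Named integer vector.
#' @export
structureLabels <- function(cohort) {
  geom <- attr(cohort, "geometry")
  if (is.null(geom)) geom <- defaultGeometry()
  stats::setNames(as.integer(geom$label), geom$structure)
}
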