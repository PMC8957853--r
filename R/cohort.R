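#' Default nucleus geometry for the synthetic cohort
#'
#' One ellipsoid per structure in the left hemisphere of the reference
#' layout; the right hemisphere is obtained by mirroring the centre about
#' the midsagittal (x = 0) plane.  Centres approximate the published
#' stereotaxic locations of the geniculate bodies.  Semi-axes are given at
#' processed-tissue (shrunken) scale, so that after correction with the
#' default shrinkage factor (~2) the volumes land in the published
#' fresh-scale range: MGB subdivisions ~20-44 mm^3, LGB ~170 mm^3 per
#' hemisphere.  Structures are spaced with enough clearance that
#' per-subject size variability cannot make labels collide.
#'
#' @return A data.frame with columns `structure`, `label`, `cx`, `cy`, `cz`
#'   (left-hemisphere centre, mm), `ax`, `ay`, `az` (semi-axes, mm).
#' @export
defaultGeometry <- function() {
  data.frame(
    structure = c("MGBv", "MGBd", "MGBm", "LGB"),
    label     = 1:4,
    cx = c(-15.0, -15.0, -15.0, -25.5),
    cy = c(-28.0, -27.0, -27.5, -24.0),
    cz = c(-15.0,  -5.0, -10.5, -10.0),
    ax = c(2.0, 2.5, 2.4, 3.8),
    ay = c(1.5, 1.75, 1.6, 2.8),
    az = c(0.8, 1.2, 1.25, 1.9),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Describes a cohort of subject brains each containing paired bilateral
#' nuclei modelled as ellipsoids with known analytic volumes.  The defaults
#' emulate a 10-subject cohort (5 female, 5 male) with roughly two-fold
#' inter-subject volume variability and small rigid+scale jitter of each
#' subject relative to the common reference grid.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param sexes character vector of `"female"`/`"male"` per subject;
#'   defaults to 5 female followed by 5 male (recycled/truncated to
#'   `nSubjects`).
#' @param geometry nucleus geometry table, see \code{\link{defaultGeometry}}.
#' @param volumeCv coefficient of variation of the per-subject isotropic
#'   nucleus volume scaling (lognormal, mean 1).
#' @param positionJitterSd sd of the per-subject translation jitter, mm.
#' @param rotationJitterSd sd of the per-subject rotation jitter, degrees.
#' @param scaleJitterSd sd of the per-subject global (whole-brain) log scale.
#' @param brainVolumeMean,brainVolumeSd fresh brain volume, mm^3.
#' @param shrinkageMean,shrinkageSd volumetric shrinkage factor f (>= 1);
#'   corrected volume = measured volume x f.
#' @param voxelSize isotropic subject voxel size, mm.
#' @param gridDim,gridOrigin subject grid dimensions and world coordinate of
#'   the centre of voxel (0,0,0).
#' @param sexEffect relative volume excess of male nuclei (0 = null cohort).
#' @param hemisphereEffect relative volume excess of left nuclei (0 = null).
#' @param seed master seed; each subject draws from its own stream derived
#'   from this seed, so cohort subsets are reproducible.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(nSubjects = 10L,
                       sexes = NULL,
                       geometry = defaultGeometry(),
                       volumeCv = 0.25,
                       positionJitterSd = 1.0,
                       rotationJitterSd = 2.0,
                       scaleJitterSd = 0.02,
                       brainVolumeMean = 1.25e6, brainVolumeSd = 1.4e5,
                       shrinkageMean = 2.0, shrinkageSd = 0.1,
                       voxelSize = 0.5,
                       gridDim = c(161L, 53L, 65L),
                       gridOrigin = c(-40, -40, -27),
                       sexEffect = 0, hemisphereEffect = 0,
                       seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  if (is.null(sexes))
    sexes <- rep(c("female", "male"), each = ceiling(nSubjects / 2))
  sexes <- rep_len(sexes, nSubjects)
  if (!all(sexes %in% c("female", "male")))
    stop("sexes must be 'female' or 'male'")
  if (volumeCv < 0 || positionJitterSd < 0 || rotationJitterSd < 0 ||
      scaleJitterSd < 0 || brainVolumeSd < 0 || shrinkageSd < 0)
    stop("all standard deviations and volumeCv must be >= 0")
  if (any(geometry$ax <= 0 | geometry$ay <= 0 | geometry$az <= 0))
    stop("all semi-axes must be > 0")
  if (voxelSize <= 0) stop("voxelSize must be > 0")
  spec <- list(nSubjects = nSubjects, sexes = sexes, geometry = geometry,
    volumeCv = volumeCv, positionJitterSd = positionJitterSd,
    rotationJitterSd = rotationJitterSd, scaleJitterSd = scaleJitterSd,
    brainVolumeMean = brainVolumeMean, brainVolumeSd = brainVolumeSd,
    shrinkageMean = shrinkageMean, shrinkageSd = shrinkageSd,
    voxelSize = voxelSize, gridDim = as.integer(gridDim),
    gridOrigin = gridOrigin, sexEffect = sexEffect,
    hemisphereEffect = hemisphereEffect, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

## deterministic per-subject seed derived from the master seed (kept < 2^31)
subjectSeed <- function(masterSeed, i) {
  as.integer((as.double(masterSeed) + 104729 * i) %% 2147483629)
}

#' Analytic ellipsoid volume
#'
#' @param a,b,c semi-axes in mm.
#' @return Volume (4/3) pi a b c in mm^3.
#' @export
ellipsoidVolume <- function(a, b, c) 4 / 3 * pi * a * b * c

rotationMatrix <- function(anglesDeg) {
  th <- anglesDeg * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each subject carries all structures of `spec$geometry` in both
#' hemispheres, mirrored about the midsagittal plane before jitter.  A single
#' rigid+scale affine per subject maps the reference layout into subject
#' space; the inverse is recorded as the subject-to-reference transform.
#' Nucleus size varies between subjects by an isotropic lognormal volume
#' factor (mean 1, CV `volumeCv`).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param volumesOnly if `TRUE`, skip voxelization and return only subject
#'   metadata and ground truth (fast path for distributional studies).
#' @return A list with elements `subjects` (data.frame: subject_id, sex, age,
#'   brain_volume_mm3, shrinkage_factor), `transforms` (list of 4x4
#'   subject-to-reference affines), `volumes` (list of
#'   \linkS4class{LabelVolume}, `NULL` if `volumesOnly`), and `groundTruth`
#'   (data.frame: subject_id, structure, hemisphere, analytic_volume_mm3,
#'   cx, cy, cz in subject space mm).
#' @export
generateCohort <- function(spec, volumesOnly = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  geom <- spec$geometry
  nStr <- nrow(geom)
  subjects <- vector("list", spec$nSubjects)
  transforms <- vector("list", spec$nSubjects)
  volumes <- if (volumesOnly) NULL else vector("list", spec$nSubjects)
  gt <- vector("list", spec$nSubjects)
  sdlog <- sqrt(log(1 + spec$volumeCv^2))

  for (i in seq_len(spec$nSubjects)) {
    set.seed(subjectSeed(spec$seed, i))
    sex <- spec$sexes[i]
    ## fixed draw order so volumesOnly and full runs agree
    vFac <- if (spec$volumeCv > 0)
      exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)) else 1
    angles <- stats::rnorm(3, 0, spec$rotationJitterSd)
    gScale <- exp(stats::rnorm(1, 0, spec$scaleJitterSd))
    shift <- stats::rnorm(3, 0, spec$positionJitterSd)
    ageRange <- if (sex == "female") c(59, 85) else c(30, 75)
    age <- round(stats::runif(1, ageRange[1], ageRange[2]))
    brainVol <- abs(stats::rnorm(1, spec$brainVolumeMean, spec$brainVolumeSd))
    shrink <- max(1, stats::rnorm(1, spec$shrinkageMean, spec$shrinkageSd))

    R <- rotationMatrix(angles)
    A <- diag(4)
    A[1:3, 1:3] <- R * gScale
    A[1:3, 4] <- shift
    sid <- sprintf("sub-%02d", i)
    subjects[[i]] <- data.frame(subject_id = sid, sex = sex, age = age,
      brain_volume_mm3 = brainVol, shrinkage_factor = shrink,
      stringsAsFactors = FALSE)
    transforms[[i]] <- solve(A)   # subject -> reference

    sLin <- vFac^(1 / 3)
    effSex <- if (sex == "male") (1 + spec$sexEffect)^(1 / 3) else 1
    rows <- vector("list", 2L * nStr)
    if (!volumesOnly)
      labs <- array(0L, spec$gridDim)
    gridAff <- diag(c(rep(spec$voxelSize, 3), 1))
    gridAff[1:3, 4] <- spec$gridOrigin

    r <- 0L
    for (h in c("left", "right")) {
      effHemi <- if (h == "left") (1 + spec$hemisphereEffect)^(1 / 3) else 1
      for (s in seq_len(nStr)) {
        cRef <- c(if (h == "left") geom$cx[s] else -geom$cx[s],
                  geom$cy[s], geom$cz[s])
        axes <- c(geom$ax[s], geom$ay[s], geom$az[s]) *
          sLin * gScale * effSex * effHemi
        cSub <- as.vector(A %*% c(cRef, 1))[1:3]
        r <- r + 1L
        rows[[r]] <- data.frame(subject_id = sid,
          structure = geom$structure[s], hemisphere = h,
          analytic_volume_mm3 = ellipsoidVolume(axes[1], axes[2], axes[3]),
          cx = cSub[1], cy = cSub[2], cz = cSub[3],
          stringsAsFactors = FALSE)
        if (!volumesOnly)
          labs <- paintEllipsoid(labs, gridAff, cSub, axes, R,
                                 geom$label[s], geom$structure[s], h)
      }
    }
    gt[[i]] <- do.call(rbind, rows)
    if (!volumesOnly)
      volumes[[i]] <- LabelVolume(labs, gridAff, spaceId = sid)
  }
  out <- list(subjects = do.call(rbind, subjects), transforms = transforms,
              volumes = volumes, groundTruth = do.call(rbind, gt))
  attr(out, "geometry") <- geom
  attr(out, "spec") <- spec
  out
}

## Voxelize one rotated ellipsoid into an existing label array, erroring on
## label collisions or grid overflow.
paintEllipsoid <- function(labs, gridAff, centre, axes, R, label,
                           structure, hemisphere) {
  d <- dim(labs)
  vox <- diag(gridAff)[1:3]
  org <- gridAff[1:3, 4]
  rad <- max(axes)
  lo <- floor((centre - rad - org) / vox)
  hi <- ceiling((centre + rad - org) / vox)
  if (any(lo < 0) || any(hi > d - 1))
    stop("structure ", structure, " (", hemisphere,
         ") exceeds the subject grid bounds")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  ## voxel-centre world coordinates within the bounding box
  xs <- org[1] + vox[1] * ii - centre[1]
  ys <- org[2] + vox[2] * jj - centre[2]
  zs <- org[3] + vox[3] * kk - centre[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  q <- g %*% R              # rows: (x-c)^T R = (R^T (x-c))^T
  inside <- (q[, 1] / axes[1])^2 + (q[, 2] / axes[2])^2 +
    (q[, 3] / axes[3])^2 <= 1
  if (!any(inside)) return(labs)
  box <- labs[ii + 1, jj + 1, kk + 1, drop = FALSE]
  insideArr <- array(inside, dim(box))
  clash <- insideArr & box != 0L
  if (any(clash))
    stop("overlapping structure labels after jitter: ", structure, " (",
         hemisphere, ") collides with label ",
         paste(sort(unique(box[clash])), collapse = ", "))
  box[insideArr] <- as.integer(label)
  labs[ii + 1, jj + 1, kk + 1] <- box
  labs
}

#' Look up the analytic ground-truth volume of a structure
#'
#' @param groundTruth the `groundTruth` data.frame from
#'   \code{\link{generateCohort}}.
#' @param structure structure name.
#' @param subjectId subject identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @return Analytic volume in mm^3.
#' @export
analyticVolume <- function(groundTruth, structure, subjectId,
                           hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  sel <- groundTruth$structure == structure &
    groundTruth$subject_id == subjectId &
    groundTruth$hemisphere == hemisphere
  if (!any(sel))
    stop("unknown structure/subject: ", structure, "/", subjectId)
  groundTruth$analytic_volume_mm3[sel]
}

#' Write cohort artifacts to disk
#'
#' Writes one NIfTI-1 label volume per subject, a metadata CSV
#' (`subject_id,sex,age,brain_volume_mm3,shrinkage_factor`), a ground-truth
#' CSV, and one 4x4 subject-to-reference transform per subject as a plain
#' text matrix (world mm, row-major).
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  meta <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$subjects, meta, row.names = FALSE)
  gtp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$groundTruth, gtp, row.names = FALSE)
  paths <- c(paths, meta, gtp)
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    tp <- file.path(dir, paste0(sid, "_to-reference.txt"))
    utils::write.table(cohort$transforms[[i]], tp, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, tp)
    if (!is.null(cohort$volumes)) {
      vp <- file.path(dir, paste0(sid, "_labels.nii.gz"))
      writeLabelVolume(cohort$volumes[[i]], vp)
      paths <- c(paths, vp)
    }
  }
  invisible(paths)
}
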