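# Programmatic phantoms used across the test files.

# digitized ball of radius r (mm) at isotropic voxel size vox, centred on
# `centre`, label 1
ballVolume <- function(r, vox, centre = c(0, 0, 0), pad = 2) {
  n <- ceiling((r + pad) / vox)
  xs <- seq(-n, n) * vox
  arr <- array(0L, rep(2L * n + 1L, 3))
  inside <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`) <= r^2
  arr[inside] <- 1L
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- centre - n * vox
  LabelVolume(arr, aff)
}

# axis-aligned box of nx x ny x nz voxels of label 1 inside a padded grid
boxVolume <- function(nx, ny, nz, vox = 0.5, pad = 2L) {
  d <- c(nx, ny, nz) + 2L * pad
  arr <- array(0L, d)
  arr[pad + seq_len(nx), pad + seq_len(ny), pad + seq_len(nz)] <- 1L
  aff <- diag(c(vox, vox, vox, 1))
  LabelVolume(arr, aff)
}

# build a SectionStack directly from a list of logical masks
makeStack <- function(masks, thickness = 0.02, interval = 15L, offset = 0L,
                      pixelSize = c(0.5, 0.5), axis = 2L) {
  n <- length(masks)
  dims <- if (n) dim(masks[[1]]) else c(1L, 1L)
  srcDim <- c(dims[1], as.integer(ceiling(n * interval * thickness / 0.5)),
              dims[2])
  new("SectionStack", subjectId = "phantom", structure = "test",
      sections = masks,
      sectionIndex = as.integer(offset + interval * (seq_len(n) - 1L)),
      thickness = thickness, interval = as.integer(interval),
      offset = as.integer(offset), axis = as.integer(axis),
      pixelSize = pixelSize, sourceAffine = diag(c(0.5, 0.5, 0.5, 1)),
      sourceDim = srcDim)
}

# exhaustive two-group permutation null: all contrasts mean(g1) - mean(g2)
# over every assignment of n1 values to group 1
exhaustiveNull <- function(values, n1) {
  apply(utils::combn(length(values), n1), 2, function(ix)
    mean(values[ix]) - mean(values[-ix]))
}

# one-structure cohort spec with controllable geometry
singleStructureSpec <- function(ax, ay, az, centre = c(-15, -27, -10), ...) {
  geom <- data.frame(structure = "test", label = 1L,
                     cx = centre[1], cy = centre[2], cz = centre[3],
                     ax = ax, ay = ay, az = az, stringsAsFactors = FALSE)
  cohortSpec(geometry = geom, ...)
}

# the 12-triangle unit cube with outward orientation
unitCubeMesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  new("SurfaceMesh", vertices = V, faces = f, structure = "cube",
      spaceId = "test")
}
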