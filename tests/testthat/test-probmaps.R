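test_that("reconstruction reproduces a constant cross-section exactly", {
  ## cylinder along the slicing axis: every section shows the same disk
  px <- 0.5
  xs <- seq(-5, 5, by = px)
  disk <- outer(xs^2, xs^2, `+`) <= 9
  arr <- array(0L, c(length(xs), 30, length(xs)))
  for (j in 1:30) arr[, j, ] <- as.integer(disk)
  aff <- diag(c(px, px, px, 1)); aff[1:3, 4] <- c(-5, 0, -5)
  cyl <- LabelVolume(arr, aff)
  st <- sliceVolume(cyl, 1, 0.020, 15L, offset = 3L)
  vTrue <- voxelCountVolume(cyl, 1)
  for (mode in c("block", "shape_based")) {
    rec <- stackToVolume(st, mode, axisPitch = 0.1)
    ## interior reproduced exactly; only the 0.3 mm end slabs are uncertain
    vRec <- voxelCountVolume(rec, 1)
    expect_lt(abs(vRec - vTrue) / vTrue, 2 * 0.3 / 15)
    mid <- labelArray(rec)[, dim(labelArray(rec))[2] %/% 2, ]
    expect_equal(mid, as.integer(disk), ignore_attr = TRUE)
  }
})

test_that("sphere reconstruction: accurate volume, better shape fidelity", {
  sph <- ballVolume(3, 0.25)
  st <- sliceVolume(sph, 1, 0.020, 15L, offset = 7L)
  vTrue <- 4 / 3 * pi * 27
  recB <- stackToVolume(st, "block")
  recS <- stackToVolume(st, "shape_based")
  errB <- abs(voxelCountVolume(recB, 1) - vTrue) / vTrue
  errS <- abs(voxelCountVolume(recS, 1) - vTrue) / vTrue
  expect_lt(errB, 0.03)
  expect_lt(errS, 0.03)
  ## volume of mismatch against the analytic sphere, evaluated at the
  ## reconstruction's voxel centres: interpolating the boundary places it
  ## better than extruding the last sampled mask
  mismatch <- function(rec) {
    arr <- labelArray(rec); d <- dim(arr); A <- affineMatrix(rec)
    xs <- A[1, 4] + (0:(d[1] - 1)) * A[1, 1]
    ys <- A[2, 4] + (0:(d[2] - 1)) * A[2, 2]
    zs <- A[3, 4] + (0:(d[3] - 1)) * A[3, 3]
    inside <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`) <= 9
    sum(xor(arr == 1L, inside)) * prod(abs(diag(A)[1:3]))
  }
  expect_lt(mismatch(recS), mismatch(recB))
})

test_that("degenerate stacks reconstruct sensibly", {
  stEmpty <- makeStack(list(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8)))
  rec <- stackToVolume(stEmpty, "block")
  expect_true(all(labelArray(rec) == 0L))
  one <- matrix(FALSE, 8, 8); one[3:5, 3:5] <- TRUE
  st1 <- makeStack(list(one))
  expect_warning(stackToVolume(st1, "shape_based"), "falling back to block")
})

test_that("nearest-neighbour resampling preserves labels and translations", {
  ball <- ballVolume(4, 0.5, centre = c(-10, -10, -10))
  ref <- LabelVolume(array(0L, dim(labelArray(ball))), affineMatrix(ball),
                     "reference")
  ## identity transform on the same grid returns the input
  m <- toReference(ball, diag(4), ref, 1L)
  expect_identical(labelArray(m), labelArray(ball))
  ## pure translation by one voxel pitch shifts the mask by one voxel
  tr <- diag(4); tr[1, 4] <- 0.5
  m2 <- toReference(ball, tr, ref, 1L)
  d1 <- dim(labelArray(ball))[1]
  expect_identical(labelArray(m2)[2:d1, , ], labelArray(ball)[1:(d1 - 1), , ])
  ## a rotated ball keeps its volume within the nearest-neighbour bound
  rot <- diag(4)
  th <- 20 * pi / 180
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  refBig <- referenceGrid(c(60, 60, 60), c(-20, -20, -20), 0.5)
  m3 <- toReference(ball, rot, refBig, 1L)
  expect_lt(abs(voxelCountVolume(m3, 1) - voxelCountVolume(ball, 1)) /
              voxelCountVolume(ball, 1), 0.02)
  ## structures falling outside the grid are an error
  far <- diag(4); far[1:3, 4] <- 500
  expect_error(toReference(ball, far, refBig, 1L), "outside the reference")
})

test_that("probability maps count overlapping subjects voxel-wise", {
  ref <- referenceGrid(c(10, 10, 10), c(0, 0, 0), 1)
  mk <- function(ix) {
    a <- array(0L, c(10, 10, 10)); a[ix] <- 1L
    LabelVolume(a, affineMatrix(ref), "reference")
  }
  masks <- c(list(mk(1:200)), lapply(1:9, function(i) mk(101:200)))
  map <- computeProbabilityMap(masks, "test")
  p <- percentMap(map)
  expect_equal(p[1], 10)            # covered by exactly one of ten
  expect_equal(p[150], 100)         # covered by all ten
  expect_equal(sort(unique(as.vector(p))), c(0L, 10L, 100L))
  ## n identical masks give 100 x mask
  same <- computeProbabilityMap(lapply(1:5, function(i) mk(31:60)), "s")
  expect_equal(percentMap(same), 100L * labelArray(mk(31:60)),
               ignore_attr = TRUE)
  ## grids must match
  other <- referenceGrid(c(10, 10, 10), c(1, 0, 0), 1)
  bad <- LabelVolume(array(1L, c(10, 10, 10)), affineMatrix(other),
                     "reference")
  expect_error(computeProbabilityMap(list(mk(1:10), bad)), "same grid")
  ## mass conservation: sum(percent)/100 x voxel volume = mean mask volume
  vv <- prod(voxelSize(map))
  expect_equal(sum(percentMap(map, rounded = FALSE)) / 100 * vv,
               mean(vapply(masks, function(m) sum(labelArray(m)) * vv,
                           numeric(1))), tolerance = 1e-12)
})

test_that("centres of mass are weighted voxel centroids in mm", {
  ref <- referenceGrid(c(21, 21, 21), c(-10, -10, -10), 1)
  one <- array(0, c(21, 21, 21)); one[4, 6, 8] <- 100
  mapOne <- new("ProbabilityMap", structure = "s", percent = one,
                nSubjects = 10L, affine = affineMatrix(ref),
                spaceId = "reference")
  expect_equal(centerOfMass(mapOne), c(x = -7, y = -5, z = -3))
  two <- one; two[6, 6, 8] <- 100
  mapTwo <- new("ProbabilityMap", structure = "s", percent = two,
                nSubjects = 10L, affine = affineMatrix(ref),
                spaceId = "reference")
  expect_equal(centerOfMass(mapTwo), c(x = -6, y = -5, z = -3))
  ## digitized ball centred at (-16, -27, -8)
  ball <- ballVolume(5, 0.5, centre = c(-16, -27, -8))
  map <- computeProbabilityMap(list(ball), "ball")
  expect_equal(centerOfMass(map, "left"), c(x = -16, y = -27, z = -8))
  empty <- new("ProbabilityMap", structure = "s",
               percent = array(0, c(3, 3, 3)), nSubjects = 1L,
               affine = diag(4), spaceId = "r")
  expect_error(centerOfMass(empty), "empty")
})

test_that("thresholding is monotone with the documented end points", {
  ref <- referenceGrid(c(8, 8, 8), c(0, 0, 0), 1)
  mk <- function(ix) {
    a <- array(0L, c(8, 8, 8)); a[ix] <- 1L
    LabelVolume(a, affineMatrix(ref), "reference")
  }
  map <- computeProbabilityMap(list(mk(1:60), mk(31:90), mk(31:60)), "t")
  m0 <- labelArray(thresholdMap(map, 0))
  m50 <- labelArray(thresholdMap(map, 50))
  m100 <- labelArray(thresholdMap(map, 100))
  expect_equal(which(m0 == 1L), 1:90)       # any overlap
  expect_equal(which(m100 == 1L), 31:60)    # intersection of all subjects
  expect_true(all(m50 >= m100) && all(m0 >= m50))  # nesting
  expect_error(thresholdMap(map, 101), "0, 100")
})
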