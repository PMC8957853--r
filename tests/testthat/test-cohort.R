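test_that("zero-variance cohorts are identical across subjects and mirrored", {
  spec <- cohortSpec(nSubjects = 2, volumeCv = 0, positionJitterSd = 0,
                     rotationJitterSd = 0, scaleJitterSd = 0, seed = 11)
  coh <- generateCohort(spec)
  gt <- coh$groundTruth
  for (s in unique(gt$structure)) {
    v <- gt$analytic_volume_mm3[gt$structure == s]
    expect_equal(max(v) - min(v), 0)
  }
  ## mirroring: left and right ground-truth volumes equal, centres mirrored
  left <- gt[gt$hemisphere == "left", ]
  right <- gt[gt$hemisphere == "right", ]
  expect_equal(left$analytic_volume_mm3, right$analytic_volume_mm3)
  expect_equal(left$cx, -right$cx)
  expect_equal(left$cy, right$cy)
  ## identical label fields (mirroring holds voxel-wise on a symmetric grid)
  expect_identical(labelArray(coh$volumes[[1]]), labelArray(coh$volumes[[2]]))
})

test_that("cohort generation is deterministic given the seed", {
  sx <- c("female", "male", "female")
  spec <- cohortSpec(nSubjects = 3, sexes = sx, seed = 42)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$groundTruth, b$groundTruth)
  expect_identical(lapply(a$volumes, labelArray), lapply(b$volumes, labelArray))
  ## subject streams are independent of cohort size: first subjects agree
  c3 <- generateCohort(cohortSpec(nSubjects = 2, sexes = sx[1:2], seed = 42))
  expect_identical(a$subjects[1:2, ], c3$subjects)
})

test_that("voxelized ellipsoids match the analytic volume", {
  ## semi-axes (4, 3, 2.5) mm -> 4/3 pi * 30 = 125.66 mm^3
  spec <- singleStructureSpec(4, 3, 2.5, nSubjects = 2, volumeCv = 0,
    positionJitterSd = 0, rotationJitterSd = 0, scaleJitterSd = 0, seed = 5)
  coh <- generateCohort(spec)
  va <- analyticVolume(coh$groundTruth, "test", "sub-01", "left")
  expect_equal(va, 4 / 3 * pi * 4 * 3 * 2.5, tolerance = 1e-12)
  vc <- voxelCountVolume(hemisphereVolume(coh$volumes[[1]], "left"), 1)
  expect_lt(abs(vc - va) / va, 0.03)
})

test_that("ellipsoidVolume is the closed form and scales homogeneously", {
  expect_equal(ellipsoidVolume(1, 1, 1), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(ellipsoidVolume(6, 5, 4), 502.65, tolerance = 1e-4)
  s <- 1.7
  expect_equal(ellipsoidVolume(s * 2, s * 3, s * 1.2),
               s^3 * ellipsoidVolume(2, 3, 1.2), tolerance = 1e-12)
})

test_that("analyticVolume rejects unknown structures", {
  coh <- generateCohort(cohortSpec(nSubjects = 2, seed = 1),
                        volumesOnly = TRUE)
  expect_error(analyticVolume(coh$groundTruth, "nucleus-X", "sub-01"),
               "unknown structure")
})

test_that("realized volume CV matches the specified CV", {
  spec <- cohortSpec(nSubjects = 400, volumeCv = 0.25, seed = 99)
  coh <- generateCohort(spec, volumesOnly = TRUE)
  gt <- coh$groundTruth
  v <- gt$analytic_volume_mm3[gt$structure == "LGB" & gt$hemisphere == "left"]
  cv <- sd(v) / mean(v)
  ## CV estimate of a lognormal at n = 400: |cv_hat - cv| < ~3 sd
  expect_lt(abs(cv - 0.25), 0.04)
  ## two-fold variability regime at cohort scale: max/min ratio over sets
  ## of 10 typically exceeds 2
  ratios <- vapply(split(v, rep(1:40, each = 10)),
                   function(x) max(x) / min(x), numeric(1))
  expect_gt(median(ratios), 2)
})

test_that("colliding or out-of-bounds structures raise informative errors", {
  geomClash <- data.frame(structure = c("A", "B"), label = 1:2,
    cx = c(-15, -14), cy = c(-27, -27), cz = c(-10, -10),
    ax = c(3, 3), ay = c(2, 2), az = c(2, 2), stringsAsFactors = FALSE)
  spec <- cohortSpec(nSubjects = 2, geometry = geomClash, volumeCv = 0,
    positionJitterSd = 0, rotationJitterSd = 0, scaleJitterSd = 0, seed = 2)
  expect_error(generateCohort(spec), "overlapping structure labels")

  spec2 <- singleStructureSpec(4, 3, 2, centre = c(-38.5, -27, -10),
    nSubjects = 2, volumeCv = 0, positionJitterSd = 0, rotationJitterSd = 0,
    scaleJitterSd = 0, seed = 2)
  expect_error(generateCohort(spec2), "exceeds the subject grid")
})

test_that("cohort artifacts round-trip through disk", {
  spec <- cohortSpec(nSubjects = 2, seed = 8)
  coh <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  meta <- read.csv(file.path(dir, "subjects.csv"))
  expect_equal(meta$subject_id, c("sub-01", "sub-02"))
  v <- readLabelVolume(file.path(dir, "sub-01_labels.nii.gz"))
  expect_identical(labelArray(v), labelArray(coh$volumes[[1]]))
  expect_equal(affineMatrix(v), affineMatrix(coh$volumes[[1]]),
               tolerance = 1e-5)
  tr <- as.matrix(read.table(file.path(dir, "sub-01_to-reference.txt")))
  expect_equal(unname(tr), coh$transforms[[1]], tolerance = 1e-12)
})
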