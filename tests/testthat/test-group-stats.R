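test_that("the permutation contrast is antisymmetric with identical p", {
  v <- c(1, 2, 1.5, 2.5, 0.5, 3)
  g <- rep(c("a", "b"), 3)
  r1 <- permutationContrast(v, factor(g, levels = c("a", "b")),
                            nIter = 2000, seed = 4)
  r2 <- permutationContrast(v, factor(g, levels = c("b", "a")),
                            nIter = 2000, seed = 4)
  expect_equal(r1$C_obs, -r2$C_obs)
  expect_equal(r1$p_value, r2$p_value)   # two-sided on |C|
})

test_that("constant values give a degenerate null with p = 1", {
  expect_warning(
    r <- permutationContrast(rep(2, 6), rep(c("a", "b"), 3), nIter = 100,
                             seed = 1),
    "degenerate")
  expect_equal(r$C_obs, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_true(r$degenerate)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration (2v2)", {
  v <- c(1, 1, 0, 0)          # group 1 = (1,1): C_obs = +1
  g <- c("hi", "hi", "lo", "lo")
  null <- exhaustiveNull(v, 2)
  pExact <- mean(null >= 1)   # one-sided exceedance, ties included: 1/6
  expect_equal(pExact, 1 / 6, tolerance = 1e-12)
  nIter <- 1e5
  r <- permutationContrast(v, factor(g, levels = c("hi", "lo")),
                           nIter = nIter, seed = 7, sided = "one")
  se <- sqrt(pExact * (1 - pExact) / nIter)
  expect_lt(abs(r$p_value - pExact), 3 * se + 2 / nIter)
})

test_that("permutation results are deterministic given the seed", {
  v <- rnorm(12)
  g <- rep(c("a", "b"), 6)
  r1 <- permutationContrast(v, g, nIter = 5000, seed = 123)
  r2 <- permutationContrast(v, g, nIter = 5000, seed = 123)
  expect_identical(r1[c("C_obs", "p_value", "exceedance_rank")],
                   r2[c("C_obs", "p_value", "exceedance_rank")])
  expect_error(permutationContrast(v, rep("a", 12), 100, 1), "two levels")
})

test_that("the interaction contrast permutes sex over subject pairs", {
  ## identical left/right values: zero contrast, degenerate null
  expect_warning(
    r0 <- interactionContrast(c(1, 2, 3, 4), c(1, 2, 3, 4),
                              c("male", "male", "female", "female"),
                              nIter = 100, seed = 1),
    "degenerate")
  expect_equal(r0$C_obs, 0)
  ## swapping all sex labels flips the sign
  l <- c(5, 6, 4, 7); r <- c(4, 4, 5, 5)
  sex <- c("male", "male", "female", "female")
  a <- interactionContrast(l, r, sex, nIter = 500, seed = 2)
  b <- interactionContrast(l, r, rev(sex), nIter = 500, seed = 2)
  expect_equal(a$C_obs, -b$C_obs)
  ## 2v2 with differences (+1,+1) males vs (-1,-1) females: exhaustive
  ## sex relabeling gives one-sided exceedance 1/6
  l2 <- c(1, 1, 0, 0); r2 <- c(0, 0, 1, 1)
  null <- exhaustiveNull(l2 - r2, 2)
  expect_equal(mean(null >= 2), 1 / 6, tolerance = 1e-12)
  rr <- interactionContrast(l2, r2, sex, nIter = 1e5, seed = 3, sided = "one")
  expect_equal(rr$C_obs, 2)
  se <- sqrt(1 / 6 * 5 / 6 / 1e5)
  expect_lt(abs(rr$p_value - 1 / 6), 3 * se + 2e-5)
  expect_error(interactionContrast(c(1, NA), c(1, 2), c("male", "female"),
                                   100, 1), "missing")
})

test_that("the paired t-test reproduces hand-computed statistics", {
  b <- c(4, 5, 6, 7)
  a <- b + c(-3, -1, -2, -2)   # mean d = -2, sd d = 0.8165
  r <- pairedTTest(a, b)
  expect_equal(r$t, -4.899, tolerance = 1e-3)
  expect_equal(r$df, 3)
  expect_equal(r$sided, "two")
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_error(pairedTTest(b, b), "zero-variance")
  expect_error(pairedTTest(b + 1, b), "zero-variance")  # constant shift
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("cohort-level contrasts run on the tidy volume table", {
  coh <- generateCohort(cohortSpec(nSubjects = 4, seed = 31))
  tab <- cohortVolumetry(coh, seed = 2)
  res <- volumeContrasts(tab, "LGB", nIter = 500, seed = 9)
  expect_named(res, c("hemisphere", "sex", "interaction"))
  for (r in res) {
    expect_s3_class(r, "permTest")
    expect_true(r$p_value > 0 && r$p_value <= 1)
    expect_equal(r$p_value, (1 + r$exceedance_rank) / (1 + r$n_iter))
  }
})
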