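#' Monte-Carlo permutation test for a two-group contrast
#'
#' The observed contrast is the difference of group means,
#' C = mean(group 1) - mean(group 2).  The null distribution is estimated by
#' randomly redistributing all values into two groups of the original sizes
#' and recomputing the contrast `nIter` times.  The p-value uses the add-one
#' estimator (1 + exceedances) / (1 + nIter); ties with the observed contrast
#' count as exceedances (conservative).  With `sided = "one"` significance
#' follows the classical randomization criterion: the observed contrast must
#' be larger than 95\% of the null draws; with `sided = "two"` (default) the
#' comparison is on absolute contrasts.
#'
#' @param values numeric vector of observations.
#' @param labels two-level grouping (factor, character or logical); group 1
#'   is the first factor level (or first value encountered).
#' @param nIter number of Monte-Carlo relabelings (>= 1).
#' @param seed RNG seed (the result is deterministic given the seed).
#' @param sided `"two"` or `"one"`.
#' @param contrastName stored in the result for reporting.
#' @return An object of class `permTest`: a list with `contrastName`,
#'   `C_obs`, `n_iter`, `exceedance_rank`, `p_value`, `sided`, `seed`,
#'   `significant` (p < 0.05), `degenerate` (all values equal) and
#'   `null_quantiles`.
#' @export
permutationContrast <- function(values, labels, nIter = 1e6, seed = 1L,
                                sided = c("two", "one"),
                                contrastName = "contrast") {
  sided <- match.arg(sided)
  nIter <- as.integer(nIter)
  if (nIter < 1L) stop("nIter must be >= 1")
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  if (length(values) != n) stop("values and labels differ in length")
  cObs <- mean(values[g1]) - mean(values[!g1])

  degenerate <- stats::var(values) == 0 || isTRUE(all(values == values[1]))
  if (degenerate) {
    res <- list(contrastName = contrastName, C_obs = cObs, n_iter = nIter,
      exceedance_rank = nIter, p_value = 1, sided = sided, seed = seed,
      significant = FALSE, degenerate = TRUE,
      null_quantiles = stats::setNames(rep(0, 3), c("5%", "50%", "95%")))
    class(res) <- "permTest"
    warning("all values identical: degenerate null, p = 1")
    return(res)
  }

  set.seed(seed)
  total <- sum(values)
  nullC <- numeric(nIter)
  for (b in seq_len(nIter)) {
    s1 <- sum(values[sample.int(n, n1)])
    nullC[b] <- s1 / n1 - (total - s1) / n2
  }
  exceed <- if (sided == "two") sum(abs(nullC) >= abs(cObs))
            else sum(nullC >= cObs)
  p <- (1 + exceed) / (1 + nIter)
  res <- list(contrastName = contrastName, C_obs = cObs, n_iter = nIter,
    exceedance_rank = exceed, p_value = p, sided = sided, seed = seed,
    significant = p < 0.05, degenerate = FALSE,
    null_quantiles = stats::quantile(nullC, c(0.05, 0.5, 0.95)))
  class(res) <- "permTest"
  res
}

#' @export
print.permTest <- function(x, ...) {
  cat("Monte-Carlo permutation test (", x$sided, "-sided): ",
      x$contrastName, "\n", sep = "")
  cat("  C_obs = ", signif(x$C_obs, 5), "; exceedances ", x$exceedance_rank,
      " / ", x$n_iter, "; p = ", signif(x$p_value, 4),
      if (x$degenerate) " (degenerate null)" else "", "\n", sep = "")
  invisible(x)
}

#' Permutation test for a sex-by-hemisphere interaction
#'
#' The interaction contrast is the mean within-subject left-minus-right
#' difference among males minus the same mean among females.  The null is
#' built by permuting sex labels across subjects while keeping each
#' subject's hemisphere pair intact.
#'
#' @param left,right per-subject values for the two hemispheres (equal
#'   length, no missing values).
#' @param sex per-subject `"female"`/`"male"` labels.
#' @param nIter,seed,sided as in \code{\link{permutationContrast}}.
#' @return A `permTest` object (contrast name `"interaction"`).
#' @export
interactionContrast <- function(left, right, sex, nIter = 1e6, seed = 1L,
                                sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(left) != length(right) || length(left) != length(sex))
    stop("left, right and sex must have equal length")
  if (anyNA(left) || anyNA(right))
    stop("missing hemisphere value")
  d <- left - right
  ## group 1 = male so that C = mean_male(d) - mean_female(d)
  permutationContrast(d, factor(sex, levels = c("male", "female")),
                      nIter = nIter, seed = seed, sided = sided,
                      contrastName = "interaction")
}

#' Paired two-sided t-test
#'
#' Thin wrapper around \code{stats::t.test(..., paired = TRUE)} with explicit
#' guards for the degenerate designs that arise with synthetic cohorts
#' (identical vectors, zero-variance differences).
#'
#' @param a,b paired per-subject values (equal length >= 2).
#' @return A list of class `pairedTTest` with `t`, `df`, `p_value`,
#'   `mean_difference` and `sided = "two"`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least two pairs")
  d <- a - b
  if (stats::var(d) == 0)
    stop("zero-variance differences: t statistic undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
              p_value = ht$p.value, mean_difference = mean(d), sided = "two")
  class(res) <- "pairedTTest"
  res
}

#' @export
print.pairedTTest <- function(x, ...) {
  cat("Paired two-sided t-test: t(", x$df, ") = ", signif(x$t, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Hemisphere, sex and interaction tests on a cohort volume table
#'
#' Runs the three permutation tests on normalized volumes of one structure:
#' hemisphere (left vs. right, treating the 2n per-hemisphere values as two
#' groups), sex (male vs. female), and their interaction (sex permutation of
#' within-subject hemisphere differences).  The sex test can use
#' per-subject bilateral sums (`mode = "per_subject"`, the default: subjects
#' are the exchangeable units, giving exact type-I control) or per-hemisphere
#' values (`mode = "per_hemisphere"`, 2 correlated values per subject, which
#' overstates the effective sample size and is anti-conservative under
#' between-subject size variability).
#'
#' @param volumes tidy volume table from \code{\link{cohortVolumetry}}.
#' @param structure structure name to test.
#' @param value column to analyze (default `"proportion"`).
#' @param mode grouping mode for the sex test.
#' @param nIter,seed,sided as in \code{\link{permutationContrast}}.
#' @return Named list of `permTest` objects: `hemisphere`, `sex`,
#'   `interaction`.
#' @export
volumeContrasts <- function(volumes, structure, value = "proportion",
                            mode = c("per_subject", "per_hemisphere"),
                            nIter = 1e4, seed = 1L,
                            sided = c("two", "one")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  v <- volumes[volumes$structure == structure, ]
  if (nrow(v) == 0L) stop("structure not found in volume table")
  v <- v[order(v$subject_id, v$hemisphere), ]
  hemi <- permutationContrast(v[[value]],
    factor(v$hemisphere, levels = c("left", "right")),
    nIter = nIter, seed = seed, sided = sided, contrastName = "hemisphere")
  if (mode == "per_subject") {
    agg <- aggregateVolumes(v, by = c("subject_id", "sex"))
    sexTest <- permutationContrast(agg[[value]],
      factor(agg$sex, levels = c("male", "female")),
      nIter = nIter, seed = seed + 1L, sided = sided, contrastName = "sex")
  } else {
    sexTest <- permutationContrast(v[[value]],
      factor(v$sex, levels = c("male", "female")),
      nIter = nIter, seed = seed + 1L, sided = sided, contrastName = "sex")
  }
  left <- v[v$hemisphere == "left", ]
  right <- v[v$hemisphere == "right", ]
  stopifnot(identical(left$subject_id, right$subject_id))
  inter <- interactionContrast(left[[value]], right[[value]], left$sex,
    nIter = nIter, seed = seed + 2L, sided = sided)
  list(hemisphere = hemi, sex = sexTest, interaction = inter)
}
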