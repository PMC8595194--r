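# Regression and rank-test helpers used by the volumetry analyses: the
# third-degree polynomial fit through stage-resolved volume shares, the
# RANSAC line through the bilateral-overlap data, and the Mann-Whitney U test.

#' Least-squares cubic fit
#'
#' Fits a third-degree polynomial through (stage, percent) data by ordinary
#' least squares and reports the coefficient of determination. Fitting
#' \code{y} and \code{100 - y} yields mirror-image curves.
#'
#' @param x predictor (developmental stage).
#' @param y response (percent share).
#' @return list with \code{kind = "poly3"}, \code{coefficients} (intercept
#'   first, length 4), \code{r_squared}, and \code{fitted}. Zero-variance
#'   \code{y} yields \code{r_squared = 0} with a warning.
#' @export
fitPoly3 <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 points for a cubic fit")
  if (length(unique(x)) < 4L) stop("rank-deficient design: need 4 distinct x")
  fit <- stats::lm(y ~ poly(x, 3, raw = TRUE))
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("zero-variance response: R^2 reported as 0")
    0
  } else 1 - ssres / sstot
  list(kind = "poly3",
       coefficients = unname(stats::coef(fit)),
       r_squared = r2,
       fitted = unname(stats::fitted(fit)))
}

#' RANSAC linear regression
#'
#' Robust line fit by random sample consensus: repeatedly fits a line through
#' two random points, counts inliers within a residual threshold, and refits
#' by least squares on the largest consensus set. Used for the left/right
#' overlap-versus-stage trend, which contains gross outliers.
#'
#' @param x,y data vectors.
#' @param residualThreshold absolute residual below which a point is an
#'   inlier; default is the median-absolute-deviation scale of \code{y}
#'   about an initial least-squares line.
#' @param seed integer seed (mandatory for reproducibility).
#' @param nIter number of random samples (default 1000).
#' @return list with \code{kind = "ransac-linear"}, \code{coefficients}
#'   (intercept, slope), logical \code{inliers}, and the threshold used.
#' @export
fitRansacLinear <- function(x, y, residualThreshold = NULL, seed,
                            nIter = 1000L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(x)) < 2L) stop("degenerate design: all x identical")
  if (missing(seed)) stop("seed is required")
  if (is.null(residualThreshold)) {
    base <- stats::lm(y ~ x)
    residualThreshold <- stats::mad(stats::residuals(base))
    if (residualThreshold == 0)
      residualThreshold <- sd(stats::residuals(base)) + .Machine$double.eps
  }
  withSeed(seed, {
    best <- NULL
    bestInl <- rep(FALSE, n)
    for (i in seq_len(nIter)) {
      s <- sample.int(n, 2L)
      if (x[s[1L]] == x[s[2L]]) next
      slope <- (y[s[2L]] - y[s[1L]]) / (x[s[2L]] - x[s[1L]])
      icpt <- y[s[1L]] - slope * x[s[1L]]
      inl <- abs(y - (icpt + slope * x)) <= residualThreshold
      if (sum(inl) > sum(bestInl)) {
        bestInl <- inl
        best <- c(icpt, slope)
      }
    }
    if (sum(bestInl) < 2L || length(unique(x[bestInl])) < 2L)
      stop("no consensus set found")
    refit <- stats::lm(y[bestInl] ~ x[bestInl])
    list(kind = "ransac-linear",
         coefficients = unname(stats::coef(refit)),
         inliers = bestInl,
         residual_threshold = residualThreshold)
  })
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (rank-sum) test with midrank tie handling.
#' Exact p-values are used for combined sample sizes up to 20 when there are
#' no ties; otherwise the normal approximation with tie correction applies.
#'
#' @param a,b numeric samples.
#' @return list with \code{U} (statistic for sample \code{a}),
#'   \code{p_value} (two-sided), and \code{exact} (logical).
#' @export
mannWhitneyU <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # fully tied samples: U at its null expectation
  list(U = unname(wt$statistic), p_value = p, exact = exact)
}
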