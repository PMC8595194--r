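test_that("AsLS baseline correction flattens drift while preserving peaks", {
  # constant trace: baseline equals the signal
  cc <- baselineCorrectAsls(rep(7, 100))
  expect_lt(max(abs(cc)), 1e-6)

  # linear drift plus transient peaks: flat residual, peaks >= 90% preserved
  n <- 300
  peakH <- 10
  y <- 5 + 0.03 * seq_len(n)
  y[100:104] <- y[100:104] + peakH
  y[220:224] <- y[220:224] + peakH
  cor <- baselineCorrectAsls(y)
  expect_lt(abs(median(cor)), 0.01 * peakH)
  expect_gte(max(cor[100:104]), 0.9 * peakH)
  expect_gte(max(cor[220:224]), 0.9 * peakH)

  expect_error(baselineCorrectAsls(c(1, NA, 3, 4, 5)), "non-finite")
  expect_error(baselineCorrectAsls(c(1, 2, 3)), "longer than 3")
})

test_that("with lambda -> Inf the AsLS baseline tends to the asymmetric straight line", {
  # the second-difference penalty's null space is the affine functions, so
  # the stiff limit is the iteratively reweighted least-squares line
  set.seed(31)
  y <- rnorm(200, 10, 1)
  y[50:55] <- y[50:55] + 20
  res <- baselineCorrectAsls(y, lambda = 1e12, p = 0.01, nIter = 10,
                             returnBaseline = TRUE)
  x <- seq_along(y)
  w <- rep(1, length(y))
  z <- fitted(stats::lm(y ~ x))
  for (i in 1:10) {
    z <- fitted(stats::lm(y ~ x, weights = w))
    w <- ifelse(y > z, 0.01, 0.99)
  }
  expect_lt(max(abs(res$baseline - z)), 0.05)
})

test_that("trace normalization maps baseline to 0 and maximum to 1", {
  tr <- c(0, 0.5, 2, 8, 3, -1, 0)
  nt <- normalizeTrace(tr)
  expect_equal(max(nt), 1)
  expect_true(all(nt >= 0 & nt <= 1))
  expect_true(attr(nt, "responsive"))
  z <- normalizeTrace(rep(0, 10))
  expect_false(attr(z, "responsive"))
})

test_that("Scott's-rule KDE peaks at a planted tight cluster and integrates to n", {
  set.seed(41)
  pos <- data.frame(ml = rnorm(40, 0.2, 0.02), ap = rnorm(40, 0.3, 0.02))
  dm <- densityEstimate(pos, group = "fsk-")
  expect_lt(abs(dm$peak[["ml"]] - 0.2), 0.05)
  expect_lt(abs(dm$peak[["ap"]] - 0.3), 0.05)
  expect_equal(dm$bandwidth[["ml"]], sd(pos$ml) * 40^(-1 / 6))

  # grid integral equals the contributing-region count within quadrature error
  dml <- diff(dm$ml[1:2]); dap <- diff(dm$ap[1:2])
  expect_equal(sum(dm$density) * dml * dap, dm$n, tolerance = 0.02)

  # two groups with disjoint planted centers separate by their argmax
  posB <- data.frame(ml = rnorm(40, 0.8, 0.02), ap = rnorm(40, 0.7, 0.02))
  dmB <- densityEstimate(posB, group = "fsk+")
  expect_gt(dmB$peak[["ml"]] - dm$peak[["ml"]], 0.2)

  # degenerate covariance exercises the 1D fallback
  expect_warning(
    fb <- densityEstimate(data.frame(ml = c(0.5, 0.5), ap = c(0.5, 0.5))),
    "singular")
  expect_null(fb$density)
  expect_error(densityEstimate(data.frame(ml = 0.1, ap = 0.1)),
               "at least 2")
})
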