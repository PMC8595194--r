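geom <- defaultTankGeometry()

mkTraj <- function(x, y, t = seq_along(x) - 1) {
  Trajectory(data.frame(t_s = t, x_mm = x, y_mm = y), geom)
}

test_that("visit segmentation: single-area, alternating, all-neutral, conservation", {
  # animal never leaves area 1 (area1 = left back quadrant)
  tr <- mkTraj(rep(50, 20), rep(80, 20))
  seg <- segmentVisits(tr)
  expect_equal(nrow(seg$visits), 1)
  expect_equal(seg$visits$duration_s, 20)
  expect_equal(seg$neutral_s, 0)

  # alternating areas every 10 s at 1-s sampling -> 10-s visits
  n <- 60
  xs <- ifelse((floor((0:(n - 1)) / 10)) %% 2 == 0, 50, 150)
  tr2 <- mkTraj(xs, rep(80, n))
  seg2 <- segmentVisits(tr2)
  expect_true(all(seg2$visits$duration_s == 10))
  expect_equal(nrow(seg2$visits), 6)

  # all samples in the neutral zone: zero visits in both areas
  tr3 <- mkTraj(rep(100, 10), rep(20, 10))
  seg3 <- segmentVisits(tr3)
  expect_equal(nrow(seg3$visits), 0)
  expect_equal(seg3$neutral_s, seg3$record_s)

  expect_error(segmentVisits(Trajectory(
    data.frame(t_s = numeric(0), x_mm = numeric(0), y_mm = numeric(0)),
    geom)), "empty")

  # conservation on generated trajectories
  for (s in 1:5) {
    tg <- simulateTrajectory(durationS = 500, seed = s)
    sg <- segmentVisits(tg)
    expect_equal(sum(sg$visits$duration_s) + sg$neutral_s, sg$record_s,
                 tolerance = 1e-9)
  }
})

test_that("average time per visit averages, clips at window edges, NA when absent", {
  visits <- data.frame(area = c(1L, 1L, 1L),
                       entry_s = c(0, 100, 200),
                       exit_s = c(10, 120, 230))
  visits$duration_s <- visits$exit_s - visits$entry_s
  tpv <- averageTimePerVisit(visits, c(0, 300))
  expect_equal(tpv[["area1_s"]], 20)
  expect_true(is.na(tpv[["area2_s"]]))

  # single 100-s visit half inside the window contributes 50 s
  v2 <- data.frame(area = 2L, entry_s = 50, exit_s = 150, duration_s = 100)
  expect_equal(averageTimePerVisit(v2, c(100, 400))[["area2_s"]], 50)
})

test_that("the 40-minute exclusion rule uses a closed bound at the limit", {
  mkEntry <- function(entryMin) {
    n <- 70 * 60
    x <- rep(100, n)   # neutral
    y <- rep(20, n)
    idx <- (entryMin * 60):(entryMin * 60 + 120)
    x[idx + 1] <- 50
    y[idx + 1] <- 80   # inside area 1
    mkTraj(x, y)
  }
  ex39 <- applyExclusion(mkEntry(39), stimulusTimeS = 0)
  expect_true(ex39$include)
  expect_equal(ex39$window, c(39 * 60, 39 * 60 + 1200))
  ex41 <- applyExclusion(mkEntry(41), stimulusTimeS = 0)
  expect_false(ex41$include)
  ex40 <- applyExclusion(mkEntry(40), stimulusTimeS = 0)
  expect_true(ex40$include)
})

test_that("paired preference test: null symmetry, exact all-positive case, guards", {
  sym <- data.frame(area1_s = c(10, 12, 14, 16, 18, 20),
                    area2_s = c(12, 10, 16, 14, 20, 18))
  expect_gt(pairedPreferenceTest(sym)$p_value, 0.9)

  pos <- data.frame(area1_s = rep(10, 9), area2_s = 10 + (1:9))
  t9 <- pairedPreferenceTest(pos)
  expect_true(t9$exact)
  expect_equal(t9$p_value, 2 / 2^9, tolerance = 1e-12)

  zero <- data.frame(area1_s = rep(3, 6), area2_s = rep(3, 6))
  tz <- pairedPreferenceTest(zero)
  expect_equal(tz$p_value, 1)
  expect_equal(tz$note, "all differences zero")
  expect_error(pairedPreferenceTest(pos[1:4, ]), "at least 5")
})

test_that("planted preference odds are recovered from per-visit averages", {
  # odds 1: ratio near 1 over a long record
  r1 <- sapply(1:6, function(s) {
    tr <- simulateTrajectory(preferenceOdds = 1, durationS = 8000, seed = s)
    tpv <- averageTimePerVisit(segmentVisits(tr), c(0, 8000))
    tpv[["area2_s"]] / tpv[["area1_s"]]
  })
  expect_lt(abs(mean(r1) - 1), 0.25)

  # odds 3 Monte-Carlo mean ratio within [2.5, 3.5]
  r3 <- sapply(1:25, function(s) {
    tr <- simulateTrajectory(preferenceOdds = 3, durationS = 10000, seed = s)
    tpv <- averageTimePerVisit(segmentVisits(tr), c(0, 10000))
    tpv[["area2_s"]] / tpv[["area1_s"]]
  })
  expect_gt(mean(r3), 2.5)
  expect_lt(mean(r3), 3.5)

  # a cohort with planted preference detects area 2
  trajs <- lapply(1:9, function(i)
    simulateTrajectory(preferenceOdds = 3, durationS = 2400, seed = 40 + i))
  res <- analyzeBehaviorCohort(trajs, stimulusTimeS = 0)
  expect_lt(res$test$p_value, 0.05)
  expect_gt(res$test$median_area2_s, res$test$median_area1_s)

  # visit rate 0: the downstream exclusion rule fires
  tr0 <- simulateTrajectory(visitRate = 0, durationS = 600, seed = 2)
  expect_false(applyExclusion(tr0, stimulusTimeS = 0)$include)
})
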