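# small deterministic recording: one planted region, step responses
tinyRecording <- function(amplitude = 10, noiseSd = 0, tuning = "AA",
                          framePeriod = 2, seed = 1) {
  scene <- data.frame(ml = 0.3, ap = 0.5, area_px = 150,
                      amplitude = amplitude, tuning = tuning)
  simulateCalciumRecording(scene, fieldDim = c(y = 48, x = 48, z = 1),
                           framePeriodS = framePeriod, noiseSd = noiseSd,
                           seed = seed)
}

test_that("protocol arithmetic: onsets spaced by ISI / frame period", {
  sim <- tinyRecording()
  on <- sim$protocol$onset_frame
  expect_true(all(diff(on) == 30))           # 60 s ISI at 2 s frames
  expect_true(all(sim$protocol$duration_s == 5))
  expect_true(all(table(sim$protocol$label) == 2))
  expect_error(StimulusProtocol(c("AA", "AA"), c(10, 11), durationS = 5,
                                framePeriod = 2), "overlap")
})

test_that("a zero-amplitude noiseless scene yields a constant movie", {
  sim <- tinyRecording(amplitude = 0)
  expect_equal(diff(range(sim$series@data)), 0)
})

test_that("difference map equals planted step amplitude and preserves sign", {
  sim <- tinyRecording(amplitude = 10)
  aaEvent <- which(sim$protocol$label == "AA")[1]
  dm <- differenceMap(sim$series, sim$protocol, aaEvent)
  inPix <- which(outer((seq_len(48) - sim$truth$y_px)^2,
                       (seq_len(48) - sim$truth$x_px)^2, `+`) <=
                   (sqrt(150 / pi))^2)
  expect_equal(unname(dm$zproj[inPix]), rep(10, length(inPix)),
               tolerance = 1e-9)
  expect_equal(max(abs(dm$zproj[-inPix])), 0, tolerance = 1e-9)

  # constant movie -> all-zero map
  simC <- tinyRecording(amplitude = 0)
  dmC <- differenceMap(simC$series, simC$protocol, aaEvent)
  expect_equal(max(abs(dmC$map)), 0)

  # negative-going artifacts are retained, not clipped
  ser <- sim$series
  ser@data[10, 10, 1, dm$peak_window] <- 0
  dmN <- differenceMap(ser, sim$protocol, aaEvent)
  expect_lt(dmN$zproj[10, 10], 0)

  # linearity: scaling the movie scales every difference
  ser2 <- sim$series
  ser2@data <- ser2@data * 3
  dm3 <- differenceMap(ser2, sim$protocol, aaEvent)
  expect_equal(dm3$map, dm$map * 3, tolerance = 1e-9)

  expect_error(differenceMap(sim$series, StimulusProtocol("AA", 2), 1),
               "before")
})

test_that("candidate extraction applies the strict 100-pixel rule and merges across stimuli", {
  mk <- function(px) {
    m <- matrix(0, 40, 40)
    m[px] <- 10
    m
  }
  big <- which(outer((1:40 - 10)^2, (1:40 - 10)^2, `+`) <= 48)    # ~150 px
  small <- which(outer((1:40 - 30)^2, (1:40 - 30)^2, `+`) <= 25)  # ~80 px
  expect_gt(length(big), 100)
  expect_lt(length(small), 100)
  cands <- extractCandidateRegions(list(AA = mk(big), AM = mk(small)),
                                   noiseFloorK = 0)
  expect_length(cands, 1)
  expect_equal(sort(cands[[1]]$pixels), sort(big))

  # two disjoint planted regions -> two candidates
  big2 <- which(outer((1:40 - 30)^2, (1:40 - 30)^2, `+`) <= 48)
  c2 <- extractCandidateRegions(list(AA = mk(big), AM = mk(big2)),
                                noiseFloorK = 0)
  expect_length(c2, 2)

  # same region responding to two stimuli is merged into one candidate
  c3 <- extractCandidateRegions(list(AA = mk(big), FSK = mk(big)),
                                noiseFloorK = 0)
  expect_length(c3, 1)
})

test_that("amplitude filter thresholds at the mean of per-region medians", {
  cands <- list(list(pixels = 1:10, size_px = 10, centroid = c(y = 1, x = 1)),
                list(pixels = 11:20, size_px = 10, centroid = c(y = 2, x = 2)))
  amp <- rbind(c(10, 10, 10), c(0.1, 0.1, 0.1))
  f <- amplitudeFilter(cands, amp)
  expect_equal(f$threshold, 5.05)
  expect_equal(f$keep, c(TRUE, FALSE))

  # single candidate whose max exceeds its own median is retained
  f1 <- amplitudeFilter(cands[1], rbind(c(1, 5, 10)))
  expect_true(f1$keep)

  # identical candidates with max == median: strict inequality removes all
  fAll <- amplitudeFilter(cands, rbind(c(3, 3, 3), c(3, 3, 3)))
  expect_false(any(fAll$keep))
  expect_error(amplitudeFilter(list(), matrix(0, 0, 0)), "empty")
})

test_that("boundary filter keeps centroids inside or on the polygon", {
  poly <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  cands <- list(list(centroid = c(y = 5, x = 5)),
                list(centroid = c(y = 5, x = 15)),
                list(centroid = c(y = 5, x = 10)))
  keep <- boundaryFilter(cands, poly)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  expect_warning(k2 <- boundaryFilter(cands, NULL), "unfiltered")
  expect_true(all(k2))
})

test_that("tuning profile applies the strict 12.5% rule with repeat averaging", {
  protocol <- StimulusProtocol(rep(c("AA", "AM", "BA"), 2),
                               c(10, 40, 70, 100, 130, 160))
  mkTrace <- function(amps) {
    tr <- numeric(200)
    for (e in seq_len(nrow(protocol)))
      tr[protocol$onset_frame[e] + 1] <- amps[[protocol$label[e]]]
    nt <- tr / max(tr, 1)
    attr(nt, "responsive") <- max(tr) > 0
    nt
  }
  t1 <- tuningProfile(mkTrace(c(AA = 1, AM = 0.10, BA = 0)), protocol, 2)
  expect_equal(t1$tuning, "AA")
  # amplitude exactly at threshold is excluded
  t2 <- tuningProfile(mkTrace(c(AA = 1, AM = 0.125, BA = 0)), protocol, 2)
  expect_equal(t2$tuning, "AA")
  t3 <- tuningProfile(mkTrace(c(AA = 1, AM = 0.13, BA = 0)), protocol, 2)
  expect_equal(t3$tuning, c("AA", "AM"))
  # all-zero trace: empty set, flagged non-responsive
  t0 <- tuningProfile(normalizeTrace(rep(0, 200)), protocol, 2)
  expect_length(t0$tuning, 0)
  expect_false(t0$responsive)
})

test_that("forskolin classification keys on FSK membership", {
  expect_equal(classifyFsk(c("AA")), "fsk-")
  expect_equal(classifyFsk(c("FSK")), "fsk+")
  expect_equal(classifyFsk(c("AA", "AM", "FSK")), "fsk+")
  expect_equal(classifyFsk(character(0)), "fsk-")
})

test_that("position normalization interpolates between landmarks", {
  lm <- list(ml = c(lateral = 10, medial = 110),
             ap = c(anterior = 20, posterior = 120))
  expect_equal(normalizePosition(c(x = 10, y = 20), lm)$ml, 0)
  expect_equal(normalizePosition(c(x = 60, y = 70), lm)$ml, 0.5)
  expect_equal(normalizePosition(c(x = 60, y = 45), lm)$ap, 0.25)
  out <- normalizePosition(c(x = 120, y = 20), lm)
  expect_false(out$in_span)
  expect_error(normalizePosition(c(x = 1, y = 1),
                                 list(ml = c(5, 5), ap = c(1, 2))),
               "coincident")
})

test_that("profile frequency table sums to 100 within groups", {
  tab <- profileFrequencyTable(c("A", "A", "A", "B"), rep("g1", 4))
  expect_equal(sort(tab$percent), c(25, 75))
  tab2 <- profileFrequencyTable(rep("AA", 5), rep("g1", 5))
  expect_equal(tab2$percent, 100)
  agg <- aggregate(percent ~ group,
                   profileFrequencyTable(c("A", "B", "A", "C"),
                                         c("g1", "g1", "g2", "g2")), sum)
  expect_true(all(abs(agg$percent - 100) < 1e-9))
})

test_that("end-to-end recovery of a noisy planted scene (single seed)", {
  sim <- simulateCalciumRecording(noiseSd = 6, driftAmplitude = 3, seed = 3)
  res <- analyzeCalciumRecording(sim$series, sim$protocol,
                                 landmarks = sim$landmarks)
  reg <- res$regions
  tr <- sim$truth
  expect_equal(nrow(reg), nrow(tr))
  hits <- 0L
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((reg$centroid_x - tr$x_px[i])^2 +
                (reg$centroid_y - tr$y_px[i])^2)
    j <- which.min(d)
    if (d[j] < 10 && reg$tuning[j] == tr$tuning[i] &&
        reg$fsk[j] == tr$fsk[i]) hits <- hits + 1L
  }
  expect_equal(hits, nrow(tr))
  # planted profile mixture recovered exactly
  expect_equal(sort(reg$tuning), sort(tr$tuning))
  # normalized positions close to planted normalized coordinates
  expect_lt(max(abs(sort(reg$ml) - sort(tr$ml))), 0.05)
})
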