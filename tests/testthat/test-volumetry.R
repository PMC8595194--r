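mask3 <- function(arr, vox = c(1, 1, 1)) BinaryMask(arr, vox)

test_that("volume shares follow counts, sum to 100 and ignore voxel size", {
  # ventral field: 640 voxels; dorsal: 360 disjoint voxels -> 64% / 36%
  a <- array(FALSE, c(12, 10, 10)); a[1:8, 1:8, 1:10] <- TRUE
  b <- array(FALSE, c(12, 10, 10)); b[9:12, 1:9, 1:10] <- TRUE
  expect_equal(sum(a), 640)
  expect_equal(sum(b), 360)
  vs <- volumeShares(mask3(a), mask3(b), stage = 52)
  expect_equal(vs$vmob_percent, 64)
  expect_equal(vs$dmob_percent, 36)
  expect_equal(vs$vmob_percent + vs$dmob_percent, 100)

  # voxel-size rescaling leaves shares unchanged
  vs2 <- volumeShares(mask3(a, c(2, 2, 5)), mask3(b, c(2, 2, 5)))
  expect_equal(vs2$vmob_percent, vs$vmob_percent)

  # symmetry and empty cases
  half1 <- array(FALSE, c(4, 4, 1)); half1[1:2, , 1] <- TRUE
  half2 <- array(FALSE, c(4, 4, 1)); half2[3:4, , 1] <- TRUE
  expect_equal(volumeShares(mask3(half1), mask3(half2))$vmob_percent, 50)
  expect_equal(volumeShares(mask3(half1),
                            mask3(array(FALSE, c(4, 4, 1))))$vmob_percent, 100)
  expect_error(volumeShares(mask3(array(FALSE, c(2, 2, 1))),
                            mask3(array(FALSE, c(2, 2, 1)))), "empty")
  expect_error(volumeShares(mask3(half1), mask3(half1)), "disjoint")
})

test_that("channel shares use the union convention", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1] <- TRUE
  b <- matrix(FALSE, 10, 10); b[6:10, 1] <- TRUE
  cs <- channelShares(a, b)
  expect_equal(cs$percent_a, 50)
  expect_equal(cs$percent_b, 50)

  # A strictly inside B with |A| = |B|/2
  b2 <- matrix(FALSE, 10, 10); b2[1:10, 1] <- TRUE
  a2 <- matrix(FALSE, 10, 10); a2[1:5, 1] <- TRUE
  cs2 <- channelShares(a2, b2)
  expect_equal(cs2$percent_a, 50)
  expect_equal(cs2$percent_b, 100)
  expect_equal(cs2$convention, "union")

  cs3 <- channelShares(matrix(FALSE, 10, 10), b2)
  expect_equal(cs3$percent_a, 0)
  expect_equal(cs3$percent_b, 100)
  expect_error(channelShares(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               "empty")
})

test_that("bilateral overlap: identity, disjoint, symmetry and per-plane bookkeeping", {
  a <- array(FALSE, c(6, 6, 3)); a[2:4, 2:4, 1:2] <- TRUE
  b <- array(FALSE, c(6, 6, 3)); b[3:5, 3:5, 2:3] <- TRUE
  mA <- mask3(a); mB <- mask3(b)
  expect_equal(bilateralOverlap(mA, mA)$percent, 100)
  d <- array(FALSE, c(6, 6, 3)); d[6, 6, 3] <- TRUE
  expect_equal(bilateralOverlap(mA, mask3(d))$percent, 0)
  ab <- bilateralOverlap(mA, mB)
  ba <- bilateralOverlap(mB, mA)
  expect_equal(ab$percent, ba$percent)
  expect_equal(sum(ab$per_plane$n_both), ab$n_both)
  expect_equal(sum(ab$per_plane$n_any), ab$n_any)
  expect_error(bilateralOverlap(mask3(array(FALSE, c(2, 2, 1))),
                                mask3(array(FALSE, c(2, 2, 1)))), "labeled")
})

test_that("planted bilateral overlap is recovered from the generator's masks", {
  sim <- simulateBilateralStack(overlap = 0.4, seed = 1)
  ov <- bilateralOverlap(sim$maskL, sim$maskR)$percent / 100
  expect_gte(ov, 0.38)
  expect_lte(ov, 0.42)

  sim0 <- simulateBilateralStack(overlap = 0, seed = 1)
  expect_equal(sum(maskData(sim0$maskL) & maskData(sim0$maskR)), 0)
  sim1 <- simulateBilateralStack(overlap = 1, seed = 1)
  expect_identical(maskData(sim1$maskL), maskData(sim1$maskR))
})

test_that("axis profile finds planted peaks, mirrors in dmob mode, flags empty channels", {
  # narrow blob at 80% of the vmob span (axis runs right edge -> left edge)
  nx <- 100
  a <- array(FALSE, c(11, nx, 3))
  edges <- c(0.5, nx + 0.5)
  xc <- 20                     # normalized position (100.5 - 20)/100 = 0.805
  a[4:8, xc, 2] <- TRUE
  b <- array(FALSE, c(11, nx, 3)); b[4:8, 48, 2] <- TRUE
  prof <- axisProfile(mask3(a), mask3(b), edges = edges, mode = "vmob")
  expect_lt(abs(prof$peak_left - 0.8), 0.011)

  # symmetric masks about the midline coincide in dmob mode
  mid <- 51
  s1 <- array(FALSE, c(11, nx, 3)); s1[4:8, mid + (5:9), 2] <- TRUE
  s2 <- array(FALSE, c(11, nx, 3)); s2[4:8, mid - (5:9), 2] <- TRUE
  pd <- axisProfile(mask3(s1), mask3(s2), midlineX = mid, edges = edges,
                    mode = "dmob")
  expect_equal(pd$count_left, pd$count_right)
  expect_equal(pd$peak_left, pd$peak_right)

  # empty channel: all-zero profile with flagged peak
  pe <- axisProfile(mask3(array(FALSE, c(11, nx, 3))), mask3(b),
                    edges = edges, mode = "vmob")
  expect_true(pe$empty_left)
  expect_true(is.na(pe$peak_left))
  expect_true(all(pe$count_left == 0))

  # landmarks inside the labeled extent are rejected
  expect_error(axisProfile(mask3(a), mask3(b), edges = c(49.5, 60.5),
                           mode = "vmob"), "bracket")
})
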