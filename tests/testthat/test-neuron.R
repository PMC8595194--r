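# hand-built trees ---------------------------------------------------------

chainTree <- function(n = 5, step = 50) {
  NeuronTree(data.frame(id = 1:n, type = c(1L, rep(3L, n - 1)),
                        x = (0:(n - 1)) * step, y = 0, z = 0,
                        radius = 1, parent = c(-1L, 1:(n - 1))))
}

test_that("critical points: unbranched path, bifurcation, soma excluded", {
  cp <- criticalPoints(chainTree(5))
  expect_equal(nrow(cp), 1)
  expect_equal(cp$kind, "endpoint")

  # one bifurcation: 1 branching, 2 endpoints
  bif <- NeuronTree(data.frame(
    id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
    x = c(0, 10, 20, 30, 30), y = c(0, 0, 0, 10, -10), z = 0,
    radius = 1, parent = c(-1L, 1L, 2L, 3L, 3L)))
  cp2 <- criticalPoints(bif)
  expect_equal(sum(cp2$kind == "branching"), 1)
  expect_equal(sum(cp2$kind == "endpoint"), 2)
  expect_false(1 %in% cp2$id)
})

test_that("malformed trees are rejected naming the offending node", {
  nodes <- data.frame(id = 1:3, type = 3L, x = 0, y = 0, z = 0, radius = 1,
                      parent = c(-1L, 3L, 2L))          # 2<->3 cycle
  expect_error(NeuronTree(nodes), "cycle")
  nodes2 <- data.frame(id = 1:3, type = 3L, x = 0, y = 0, z = 0, radius = 1,
                       parent = c(-1L, -1L, 2L))        # two roots
  expect_error(NeuronTree(nodes2), "exactly one root")
  nodes3 <- data.frame(id = 1:3, type = 3L, x = 0, y = 0, z = 0, radius = 1,
                       parent = c(-1L, 1L, 9L))         # orphan
  expect_error(NeuronTree(nodes3), "orphan node 3")
})

test_that("tuft rule: more than 5 points within the radius form exactly one tuft", {
  mkPts <- function(n, center = c(0, 0, 0), spread = 4) {
    set.seed(n)
    data.frame(id = seq_len(n), kind = "endpoint",
               x = center[1] + runif(n, -spread, spread),
               y = center[2] + runif(n, -spread, spread),
               z = center[3] + runif(n, -spread, spread))
  }
  six <- detectTufts(mkPts(6))
  expect_length(six$clusters, 1)
  expect_length(six$noise_ids, 0)

  five <- detectTufts(mkPts(5))
  expect_length(five$clusters, 0)
  expect_length(five$noise_ids, 5)

  # two 8-point groups 100 um apart: two tufts with correct memberships
  g1 <- mkPts(8)
  g2 <- mkPts(8, center = c(100, 0, 0))
  g2$id <- g2$id + 8L
  both <- rbind(g1, g2)
  tf <- detectTufts(both)
  expect_length(tf$clusters, 2)
  mem <- clusterSets(lapply(tf$clusters, `[[`, "member_ids"))
  expect_equal(mem, list(1:8, 9:16))
})

test_that("tuft detection equals the brute-force radius-graph oracle on random sets", {
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(20:120, 1)
    xyz <- cbind(runif(n, 0, 120), runif(n, 0, 120), runif(n, 0, 60))
    pts <- data.frame(id = seq_len(n), kind = "endpoint",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    got <- detectTufts(pts, eps = 15, minCount = 6)
    want <- oracleDbscan(xyz, seq_len(n), eps = 15, minCount = 6)
    expect_equal(clusterSets(lapply(got$clusters, `[[`, "member_ids")),
                 clusterSets(want))
  }
})

test_that("convex hull volumes: closed forms, degeneracies, monotonicity", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  expect_equal(convexHullVolume(cube)$volume, 1000, tolerance = 1e-12)

  s <- 10
  tet <- s * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                   c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(convexHullVolume(tet)$volume, sqrt(2) / 12 * s^3,
               tolerance = 1e-9)

  flat <- convexHullVolume(cbind(runif(10), runif(10), 0))
  expect_equal(flat$volume, 0)
  expect_true(flat$degenerate)
  expect_true(convexHullVolume(matrix(runif(9), 3))$degenerate)

  # adding points never decreases the hull volume
  set.seed(55)
  pts <- matrix(runif(60, 0, 50), ncol = 3)
  v0 <- convexHullVolume(pts[1:10, ])$volume
  for (k in seq(12, 20, 2)) {
    v1 <- convexHullVolume(pts[1:k, ])$volume
    expect_gte(v1, v0 - 1e-9)
    v0 <- v1
  }
})

test_that("soma-tuft path distance sums edges and bounds the Euclidean distance", {
  # straight 200-um path
  straight <- chainTree(5, step = 50)
  d <- tuftSomaDistance(straight, memberIds = 5L)
  expect_equal(d$path_um, 200)

  # L-shaped path: 100 + 150 um legs
  ell <- NeuronTree(data.frame(
    id = 1:6, type = c(1L, rep(3L, 5)),
    x = c(0, 50, 100, 100, 100, 100), y = c(0, 0, 0, 50, 100, 150), z = 0,
    radius = 1, parent = c(-1L, 1:5)))
  dl <- tuftSomaDistance(ell, memberIds = 6L)
  expect_equal(dl$path_um, 250)
  expect_equal(dl$euclidean_um, sqrt(100^2 + 150^2))
  expect_gte(dl$path_um, dl$euclidean_um)

  expect_error(tuftSomaDistance(straight, memberIds = 99L), "not found")
})

test_that("inter-tuft distance is the mean pairwise centroid distance", {
  mkCl <- function(c3) list(member_ids = 1L, centroid = c3, n = 1L)
  two <- list(mkCl(c(0, 0, 0)), mkCl(c(146, 0, 0)))
  expect_equal(interTuftDistance(two), 146)
  three <- list(mkCl(c(0, 0, 0)), mkCl(c(100, 0, 0)), mkCl(c(200, 0, 0)))
  expect_equal(interTuftDistance(three), (100 + 200 + 100) / 3)
  expect_true(is.na(interTuftDistance(two[1])))
})

test_that("branch classification matches the uni-tufted archetype and generator truth", {
  sim <- simulateNeuron(nTufts = 1L, nPrimaryTufted = 1L, nPrimaryBasal = 2L,
                        seed = 4)
  p <- morphometricProfile(sim$tree)
  expect_equal(p$n_tufts, 1)
  expect_equal(p$primary_tufted, 1)
  expect_equal(p$primary_basal, 2)
  expect_true(is.na(p$mean_inter_tuft_distance_um))

  # no tufts: all branches basal
  br <- classifyBranches(chainTree(4), clusters = list())
  expect_equal(br$primary_tufted + br$secondary_tufted, 0)
  expect_equal(br$primary_basal, 1)

  # planted (2 primary tufted, 1 primary basal)
  sim2 <- simulateNeuron(nTufts = 3L, nPrimaryTufted = 2L,
                         nPrimaryBasal = 1L, seed = 6)
  p2 <- morphometricProfile(sim2$tree)
  expect_equal(p2$n_tufts, 3)
  expect_equal(p2$primary_tufted, 2)
  expect_equal(p2$primary_basal, 1)

  # partitions are exhaustive and disjoint over all branches
  cp <- criticalPoints(sim2$tree)
  tufts <- detectTufts(cp)
  br2 <- classifyBranches(sim2$tree, tufts$clusters)
  expect_equal(nrow(br2$branches),
               br2$primary_tufted + br2$primary_basal +
                 br2$secondary_tufted + br2$secondary_basal)
})

test_that("generator trees honor planted structure and SWC round-trips byte-identically", {
  sim <- simulateNeuron(nTufts = 2L, pointsPerTuft = 8L, seed = 12)
  cp <- criticalPoints(sim$tree)
  expect_gte(nrow(cp), 2 * 8)
  # each planted tuft contributes its points within the spread
  tufts <- detectTufts(cp)
  expect_length(tufts$clusters, 2)
  for (cl in tufts$clusters) expect_gte(cl$n, 8)
  # recovered memberships equal planted labels
  planted <- split(sim$truth$node_id[sim$truth$tuft > 0],
                   sim$truth$tuft[sim$truth$tuft > 0])
  expect_equal(clusterSets(lapply(tufts$clusters, `[[`, "member_ids")),
               clusterSets(planted))

  # path distance >= Euclidean for every tuft (triangle inequality)
  for (cl in tufts$clusters) {
    d <- tuftSomaDistance(sim$tree, cl$member_ids)
    expect_gte(d$path_um, d$euclidean_um - 1e-9)
  }

  f1 <- tempfile(fileext = ".swc"); f2 <- tempfile(fileext = ".swc")
  writeSWC(simulateNeuron(nTufts = 2L, seed = 12)$tree, f1)
  writeSWC(simulateNeuron(nTufts = 2L, seed = 12)$tree, f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- readSWC(f1)
  expect_equal(treeNodes(rt)$parent, treeNodes(sim$tree)$parent)
  expect_equal(treeNodes(rt)$x, treeNodes(sim$tree)$x, tolerance = 1e-4)
})

test_that("population comparison: null case, planted shift, tuft-class shares", {
  mkPop <- function(tufts, seedBase) do.call(rbind, lapply(
    seq_along(tufts), function(i)
      morphometricProfile(simulateNeuron(nTufts = tufts[i],
                                         seed = seedBase + i)$tree)))
  popA <- mkPop(rep(1L, 10), 100)
  popB <- mkPop(rep(3L, 10), 200)
  cmp <- populationCompare(popA, popB, labels = c("vmob", "dmob"))
  row <- cmp$tests[cmp$tests$descriptor == "n_tufts", ]
  expect_lt(row$p_value, 0.01)
  expect_equal(row$median_a, 1)
  expect_equal(row$median_b, 3)
  # inter-tuft distance absent in the all-uni population -> omitted
  expect_true("mean_inter_tuft_distance_um" %in% cmp$omitted)

  # identical populations: p ~ 1 on every tested descriptor
  same <- populationCompare(popA, popA)
  expect_true(all(same$tests$p_value > 0.9))

  # population of 18 with 10 uni-tufted -> uni share 55.6%
  pop18 <- mkPop(c(rep(1L, 10), rep(2L, 4), rep(3L, 4)), 300)
  sh <- populationCompare(pop18, popB)$tuft_shares
  expect_equal(sh$uni_percent[1], 100 * 10 / 18, tolerance = 1e-9)
})
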