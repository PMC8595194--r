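# Synthetic-data generators. Every generator plants recoverable ground truth
# (overlap fractions, tuning profiles, tuft memberships, side preferences),
# draws all randomness from one private seeded stream per call, and is
# bit-reproducible under a fixed seed.

# sphere-sphere intersection volume for equal radii r at center distance d
.lens_volume <- function(d, r) {
  ifelse(d >= 2 * r, 0, pi * (2 * r - d)^2 * (d + 4 * r) / 12)
}

#' Simulate a bilaterally traced projection-field stack
#'
#' Emulates a two-dye tracing of left- and right-origin axonal projections:
#' paired spherical Gaussian blobs whose half-maximum footprints overlap by a
#' controllable target fraction (doubly-labeled voxels relative to all
#' labeled voxels). The pair distance is solved analytically from the
#' sphere-lens volume so the planted fraction is recovered within about 2
#' percentage points before noise. A third, blue channel carries the
#' autofluorescence field only.
#'
#' @param gridDim voxel grid dimensions \code{c(y, x, z)}.
#' @param voxelSizeUm micrometers per voxel (isotropic scalar or length 3).
#' @param overlap target overlap fraction in \code{[0, 1]}.
#' @param blobsPerSide number of blob pairs (default 2).
#' @param blobRadiusUm half-maximum blob radius in micrometers (default 8).
#' @param peak blob peak intensity in arbitrary units (default 100).
#' @param noiseSd additive Gaussian noise sd (default 0).
#' @param autofluorLevel tissue autofluorescence level added to every channel
#'   (default 5).
#' @param seed integer seed; fixes the output bit-exactly.
#' @return list with \code{stack} (a [VoxelStack-class] with channels
#'   \code{left}, \code{right}, \code{blue}), ground-truth masks
#'   \code{maskL}, \code{maskR} ([BinaryMask-class]), and \code{truth}
#'   (planted overlap, pair distance, centers).
#' @export
simulateBilateralStack <- function(gridDim = c(y = 80, x = 80, z = 64),
                                   voxelSizeUm = 1, overlap = 0.4,
                                   blobsPerSide = 2L, blobRadiusUm = 8,
                                   peak = 100, noiseSd = 0,
                                   autofluorLevel = 5, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1, all(gridDim > 0), blobRadiusUm > 0,
            blobsPerSide >= 1L)
  if (length(voxelSizeUm) == 1L) voxelSizeUm <- rep(voxelSizeUm, 3L)
  r <- blobRadiusUm
  vox <- voxelSizeUm
  # pair center distance from the target fraction f = I / (2 n V - I)
  V <- 4 / 3 * pi * r^3
  n <- blobsPerSide
  if (overlap == 0) {
    d <- 2 * r + 2 * max(vox)          # safely disjoint after voxelization
  } else if (overlap == 1) {
    d <- 0
  } else {
    iTarget <- 2 * V * overlap / (1 + overlap)   # per pair
    d <- stats::uniroot(function(dd) .lens_volume(dd, r) - iTarget,
                        c(0, 2 * r), tol = 1e-10)$root
  }
  ny <- gridDim[[1]]; nx <- gridDim[[2]]; nz <- gridDim[[3]]
  ext <- c(ny * vox[1], nx * vox[2], nz * vox[3])   # physical extent, um
  margin <- r + d / 2 + 2 * max(vox)
  if (any(ext < 2 * margin))
    stop("infeasible geometry: blobs cannot fit in the grid")

  withSeed(seed, {
    # rejection-sample a full pair-center configuration, restarting when a
    # placement dead-ends
    centers <- NULL
    for (restart in seq_len(200L)) {
      centers <- matrix(NA_real_, 0, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          cand <- c(runif(1, margin, ext[1] - margin),
                    runif(1, margin, ext[2] - margin),
                    runif(1, margin, ext[3] - margin))
          if (!nrow(centers) ||
              min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
                2 * r + d + 2) {
            placed <- TRUE
            break
          }
        }
        if (!placed) break
        centers <- rbind(centers, cand)
      }
      if (nrow(centers) == n) break
    }
    if (is.null(centers) || nrow(centers) < n)
      stop("infeasible geometry: could not place blob pairs")
    # the two blobs of a pair are offset along x by +/- d/2
    offs <- c(0, d / 2, 0)
    cL <- sweep(centers, 2, offs)
    cR <- sweep(centers, 2, -offs)

    py <- (seq_len(ny) - 0.5) * vox[1]
    px <- (seq_len(nx) - 0.5) * vox[2]
    pz <- (seq_len(nz) - 0.5) * vox[3]
    # flat-core blob with a steep shoulder: intensity = peak *
    # exp(-(d^2 / (2 sigma^2))^3), sigma chosen so the half-maximum surface
    # sits exactly at the planted radius r; the steep edge makes the voxel
    # footprint insensitive to the exact binarization threshold
    sigma2 <- r^2 / (2 * log(2)^(1 / 3))
    field <- function(cs) {
      acc <- array(0, c(ny, nx, nz))
      for (k in seq_len(nrow(cs))) {
        dy2 <- (py - cs[k, 1])^2
        dx2 <- (px - cs[k, 2])^2
        dz2 <- (pz - cs[k, 3])^2
        d2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
        acc <- acc + peak * exp(-(d2 / (2 * sigma2))^3)
      }
      acc
    }
    maskOf <- function(cs) {
      acc <- array(FALSE, c(ny, nx, nz))
      for (k in seq_len(nrow(cs))) {
        dy2 <- (py - cs[k, 1])^2
        dx2 <- (px - cs[k, 2])^2
        dz2 <- (pz - cs[k, 3])^2
        acc <- acc | (outer(outer(dy2, dx2, `+`), dz2, `+`) <= r^2)
      }
      acc
    }
    fL <- field(cL); fR <- field(cR)
    mL <- maskOf(cL); mR <- maskOf(cR)
    noise <- function() array(
      if (noiseSd > 0) rnorm(ny * nx * nz, 0, noiseSd) else 0,
      c(ny, nx, nz))
    chL <- pmax(fL + autofluorLevel + noise(), 0)
    chR <- pmax(fR + autofluorLevel + noise(), 0)
    chB <- pmax(autofluorLevel + noise(), 0)
    stack <- VoxelStack(list(chL, chR, chB), voxelSize = vox,
                        channels = c("left", "right", "blue"))
    list(stack = stack,
         maskL = BinaryMask(mL, vox, list(channel = "left",
                                          method = "ground_truth")),
         maskR = BinaryMask(mR, vox, list(channel = "right",
                                          method = "ground_truth")),
         truth = list(overlap = overlap, pair_distance_um = d,
                      centers_left = cL, centers_right = cR,
                      blob_radius_um = r))
  })
}

#' Default planted calcium scene
#'
#' Twelve non-overlapping glomerular regions spanning the six most frequent
#' tuning-profile classes (two regions each): amino acids only, amines only,
#' amino acids + amines, forskolin only, amines + forskolin, and amino
#' acids + forskolin. Forskolin-responsive regions are planted medially
#' (ML > 0.6) and forskolin-non-responsive regions laterally (ML < 0.4),
#' reproducing the two processing streams.
#'
#' @param amplitude response amplitude in arbitrary units (default 30).
#' @param areaPx planted region area in pixels (default 180).
#' @return data.frame with columns \code{ml}, \code{ap}, \code{area_px},
#'   \code{amplitude}, \code{tuning}.
#' @export
defaultCalciumScene <- function(amplitude = 30, areaPx = 180) {
  lateral <- data.frame(
    ml = rep(c(0.15, 0.3), times = 3),
    ap = seq(0.1, 0.9, length.out = 6),
    tuning = rep(c("AA", "AM", "AA+AM"), each = 2))
  medial <- data.frame(
    ml = rep(c(0.7, 0.85), times = 3),
    ap = seq(0.1, 0.9, length.out = 6),
    tuning = rep(c("FSK", "AM+FSK", "AA+FSK"), each = 2))
  scene <- rbind(lateral, medial)
  scene$area_px <- areaPx
  scene$amplitude <- amplitude
  scene[, c("ml", "ap", "area_px", "amplitude", "tuning")]
}

#' Simulate a volumetric odor-response calcium recording
#'
#' Builds a 4D movie with planted circular responsive regions. Each stimulus
#' presentation adds, to the pixels of every region tuned to it, a step of
#' the region's amplitude lasting the stimulus duration followed by an
#' exponential decay (tau, default 4 s). The positive-control mixture
#' (\code{MIX}) activates every region tuned to at least one odorant class;
#' the negative control (\code{RINGER}) activates none. Global sinusoidal
#' baseline drift and Gaussian noise are added on top.
#'
#' @param scene data.frame of planted regions (see [defaultCalciumScene()]):
#'   normalized \code{ml}, \code{ap} centroids, \code{area_px},
#'   \code{amplitude}, \code{tuning} ("+"-separated subset of AA, AM, BA,
#'   FSK).
#' @param fieldDim image dimensions \code{c(y, x, z)} (default 128 x 128 x 2).
#' @param framePeriodS seconds per volumetric frame (default 2).
#' @param stimuli stimulus order within one repeat block.
#' @param repeats number of blocks (default 2; at least 2).
#' @param durationS stimulus duration (default 5 s).
#' @param isiS inter-stimulus interval (default 60 s).
#' @param baseline baseline fluorescence (default 100 a.u.).
#' @param noiseSd Gaussian noise sd (default 0).
#' @param driftAmplitude amplitude of a one-cycle sinusoidal baseline drift
#'   (default 0).
#' @param tauS decay time constant after stimulus offset (default 4 s).
#' @param leadInFrames frames before the first onset (default 10).
#' @param seed integer seed.
#' @return list with \code{series} ([RecordingSeries-class]),
#'   \code{protocol}, \code{truth} (per-region table with pixel positions,
#'   normalized coordinates, tuning and fsk class), and \code{landmarks}
#'   for [normalizePosition()].
#' @export
simulateCalciumRecording <- function(scene = defaultCalciumScene(),
                                     fieldDim = c(y = 128, x = 128, z = 2),
                                     framePeriodS = 2,
                                     stimuli = c("MIX", "RINGER", "AA", "AM",
                                                 "BA", "FSK"),
                                     repeats = 2L, durationS = 5, isiS = 60,
                                     baseline = 100, noiseSd = 0,
                                     driftAmplitude = 0, tauS = 4,
                                     leadInFrames = 10L, seed = 1L) {
  stopifnot(repeats >= 2L, durationS > 0, isiS > 0, all(scene$area_px > 0))
  ny <- fieldDim[[1]]; nx <- fieldDim[[2]]; nz <- fieldDim[[3]]
  # landmark span of the projection field within the image
  landmarks <- list(ml = c(lateral = 8, medial = nx - 8),
                    ap = c(anterior = 8, posterior = ny - 8))
  cx <- landmarks$ml[1] + scene$ml * diff(landmarks$ml)
  cy <- landmarks$ap[1] + scene$ap * diff(landmarks$ap)
  rad <- sqrt(scene$area_px / pi)
  if (any(cx < 1 | cx > nx | cy < 1 | cy > ny))
    stop("planted centroids must lie within the field")
  nR <- nrow(scene)
  if (nR > 1L) {
    cd <- as.matrix(dist(cbind(cx, cy)))
    sep <- outer(rad, rad, `+`)
    diag(cd) <- Inf
    if (any(cd <= sep)) stop("overlapping planted regions")
  }

  isiFrames <- round(isiS / framePeriodS)
  events <- expand.grid(stim = seq_along(stimuli), rep = seq_len(repeats))
  events <- events[order(events$rep, events$stim), ]
  onsets <- leadInFrames + 1L + (seq_len(nrow(events)) - 1L) * isiFrames
  protocol <- StimulusProtocol(stimuli[events$stim], onsets,
                               durationS = durationS,
                               repeatIndex = events$rep)
  nT <- max(onsets) + isiFrames

  # pixel masks per region (applied to every z plane)
  gy <- seq_len(ny); gx <- seq_len(nx)
  pixels <- lapply(seq_len(nR), function(i) {
    which(outer((gy - cy[i])^2, (gx - cx[i])^2, `+`) <= rad[i]^2)
  })
  tuningSets <- strsplit(scene$tuning, "+", fixed = TRUE)
  odorants <- c("AA", "AM", "BA")
  respondsTo <- function(i, label) {
    ts <- tuningSets[[i]]
    if (label == "RINGER") return(FALSE)
    if (label == "MIX") return(length(intersect(ts, odorants)) > 0L)
    label %in% ts
  }

  tFrames <- seq_len(nT)
  kernel <- function(onset) {
    tt <- (tFrames - onset) * framePeriodS
    k <- numeric(nT)
    during <- tt >= 0 & tt < durationS
    after <- tt >= durationS
    k[during] <- 1
    k[after] <- exp(-(tt[after] - durationS) / tauS)
    k
  }

  withSeed(seed, {
    tdrift <- if (driftAmplitude > 0)
      driftAmplitude * sin(2 * pi * tFrames / nT) else numeric(nT)
    plane <- matrix(baseline, ny, nx)
    movie <- array(0, c(ny, nx, nz, nT))
    respPlane <- matrix(0, ny * nx, nT)
    for (e in seq_len(nrow(protocol))) {
      k <- kernel(protocol$onset_frame[e])
      for (i in seq_len(nR)) {
        if (respondsTo(i, protocol$label[e]))
          respPlane[pixels[[i]], ] <- respPlane[pixels[[i]], ] +
            rep(scene$amplitude[i] * k, each = length(pixels[[i]]))
      }
    }
    baseT <- baseline + tdrift
    for (t in tFrames) {
      fr <- matrix(baseT[t], ny, nx) + matrix(respPlane[, t], ny, nx)
      for (z in seq_len(nz)) movie[, , z, t] <- fr
    }
    if (noiseSd > 0)
      movie <- movie + array(rnorm(length(movie), 0, noiseSd), dim(movie))
    movie <- pmax(movie, 0)
    series <- RecordingSeries(movie, framePeriod = framePeriodS)
    truth <- data.frame(
      id = seq_len(nR), ml = scene$ml, ap = scene$ap,
      x_px = cx, y_px = cy,
      area_px = lengths(pixels),
      amplitude = scene$amplitude,
      tuning = vapply(tuningSets, function(ts)
        paste(sort(ts), collapse = "+"), character(1)),
      fsk = vapply(tuningSets, classifyFsk, character(1)))
    list(series = series, protocol = protocol, truth = truth,
         landmarks = landmarks)
  })
}

#' Simulate a multi-tufted projection neuron
#'
#' Builds a rooted tree (soma = root) with a planted number of dendritic
#' tufts: each tuft contributes its points-per-tuft branching/endpoints
#' within the tuft spread of its center, tuft centers are mutually separated
#' by at least the requested separation, and blunt basal neurites contribute
#' sparse endpoints. Tufts are distributed over the primary tufted dendrites
#' round-robin.
#'
#' @param nTufts planted tuft count (>= 1).
#' @param pointsPerTuft critical points per tuft (>= 2; default 8).
#' @param tuftSpreadUm radius of the tuft point cloud (default 6; must be
#'   well below the clustering radius).
#' @param tuftSeparationUm minimum distance between tuft centers (default
#'   100; must exceed twice the clustering radius for unambiguous recovery).
#' @param somaPos soma position, micrometers (default origin).
#' @param nPrimaryTufted number of primary tufted dendrites (default
#'   \code{min(nTufts, 2)}).
#' @param nPrimaryBasal number of primary basal neurites (default 2).
#' @param clusterRadiusUm downstream clustering radius used only for spec
#'   validation (default 15).
#' @param seed integer seed.
#' @return list with \code{tree} ([NeuronTree-class]), \code{truth}
#'   (data.frame: critical-point node id, planted tuft label, 0 = blunt) and
#'   \code{counts} (planted descriptor values).
#' @export
simulateNeuron <- function(nTufts = 1L, pointsPerTuft = 8L, tuftSpreadUm = 6,
                           tuftSeparationUm = 100, somaPos = c(0, 0, 0),
                           nPrimaryTufted = min(nTufts, 2L),
                           nPrimaryBasal = 2L, clusterRadiusUm = 15,
                           seed = 1L) {
  stopifnot(nTufts >= 1L, pointsPerTuft >= 2L, tuftSpreadUm > 0,
            nPrimaryTufted >= 1L, nPrimaryTufted <= nTufts,
            nPrimaryBasal >= 0L)
  if (tuftSpreadUm >= clusterRadiusUm)
    stop("tuft spread must be below the clustering radius")
  if (nTufts > 1L && tuftSeparationUm <= 2 * clusterRadiusUm)
    stop("inter-tuft separation must exceed twice the clustering radius")

  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(-1, 0, 0), c(0, -1, 0),
                c(0.7071, 0.7071, 0), c(-0.7071, 0.7071, 0),
                c(0.7071, 0, 0.7071))
  if (nTufts > nrow(dirs)) stop("too many tufts requested")
  R <- max(1.05 * tuftSeparationUm / sqrt(2), 150)
  tuftCenters <- sweep(dirs[seq_len(nTufts), , drop = FALSE] * R, 2, -somaPos)

  withSeed(seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = somaPos[1], y = somaPos[2],
                        z = somaPos[3], radius = 5, parent = -1L)
    nextId <- 2L
    addNode <- function(pos, parent, type = 3L, radius = 0.5) {
      nodes <<- rbind(nodes, data.frame(id = nextId, type = type,
                                        x = pos[1], y = pos[2], z = pos[3],
                                        radius = radius, parent = parent))
      id <- nextId
      nextId <<- nextId + 1L
      id
    }
    addChain <- function(from, fromPos, toPos, stepUm = 25) {
      v <- toPos - fromPos
      len <- sqrt(sum(v^2))
      nSeg <- max(1L, ceiling(len / stepUm))
      parent <- from
      for (s in seq_len(nSeg)) {
        pos <- fromPos + v * s / nSeg
        parent <- addNode(pos, parent)
      }
      parent
    }
    somaXYZ <- somaPos
    assignment <- rep(seq_len(nPrimaryTufted), length.out = nTufts)
    truth <- data.frame(node_id = integer(0), tuft = integer(0))
    for (stem in seq_len(nPrimaryTufted)) {
      myTufts <- which(assignment == stem)
      first <- tuftCenters[myTufts[1L], ]
      if (length(myTufts) == 1L) {
        entry <- addChain(1L, somaXYZ, first)
        entries <- data.frame(tuft = myTufts[1L], node = entry)
      } else {
        forkPos <- colMeans(tuftCenters[myTufts, , drop = FALSE]) / 2
        fork <- addChain(1L, somaXYZ, forkPos)
        entries <- data.frame(tuft = integer(0), node = integer(0))
        for (tj in myTufts) {
          e <- addChain(fork, forkPos, tuftCenters[tj, ])
          entries <- rbind(entries, data.frame(tuft = tj, node = e))
        }
      }
      for (rr in seq_len(nrow(entries))) {
        tj <- entries$tuft[rr]
        entry <- entries$node[rr]
        truth <- rbind(truth, data.frame(node_id = entry, tuft = tj))
        cen <- tuftCenters[tj, ]
        for (leaf in seq_len(pointsPerTuft - 1L)) {
          jit <- runif(3, -1, 1)
          jit <- jit / sqrt(sum(jit^2)) * runif(1, 0.2, 1) * tuftSpreadUm
          leafId <- addNode(cen + jit, entry)
          truth <- rbind(truth, data.frame(node_id = leafId, tuft = tj))
        }
      }
    }
    basalDirs <- rbind(c(0, 0, -1), c(-0.7071, -0.7071, 0),
                       c(0, -0.7071, -0.7071), c(-0.7071, 0, -0.7071))
    for (b in seq_len(nPrimaryBasal)) {
      dirB <- basalDirs[(b - 1L) %% nrow(basalDirs) + 1L, ]
      endB <- somaXYZ + dirB * 80
      e <- addChain(1L, somaXYZ, endB)
      nodes$type[nodes$id == e] <- 4L
      truth <- rbind(truth, data.frame(node_id = e, tuft = 0L))
    }
    tree <- NeuronTree(nodes)
    list(tree = tree, truth = truth,
         counts = list(n_tufts = nTufts,
                       points_per_tuft = pointsPerTuft,
                       primary_tufted = nPrimaryTufted,
                       primary_basal = nPrimaryBasal))
  })
}

#' Simulate a two-area choice-tank trajectory
#'
#' Two-state semi-Markov dwell process: the animal alternates between the
#' shared neutral zone (exponential dwell with rate \code{visitRate}) and a
#' randomly chosen area; dwell times in area 1 are exponential with mean
#' \code{meanDwellS}, in area 2 with mean \code{preferenceOdds *
#' meanDwellS}, so the long-run expected time per visit ratio (area 2 /
#' area 1) equals the planted preference odds. Positions are sampled
#' uniformly inside the current zone's polygon.
#'
#' @param geometry tank geometry (see [defaultTankGeometry()]).
#' @param preferenceOdds relative dwell multiplier for area 2 (> 0).
#' @param meanDwellS mean dwell per visit in area 1, seconds (default 13).
#' @param visitRate rate of leaving the neutral zone, per second (default
#'   0.05); 0 means the animal never enters either area.
#' @param durationS record duration in seconds (default 3600).
#' @param dtS sampling period in seconds (default 1).
#' @param seed integer seed.
#' @return A [Trajectory-class]; planted parameters in attribute
#'   \code{"truth"}.
#' @export
simulateTrajectory <- function(geometry = defaultTankGeometry(),
                               preferenceOdds = 1, meanDwellS = 13,
                               visitRate = 0.05, durationS = 3600, dtS = 1,
                               seed = 1L) {
  stopifnot(preferenceOdds > 0, meanDwellS > 0, visitRate >= 0,
            durationS > 0, dtS > 0)
  withSeed(seed, {
    # state sequence: 0 = neutral, 1 = area1, 2 = area2
    stateSeq <- integer(0)
    dwell <- numeric(0)
    tAcc <- 0
    state <- 0L
    while (tAcc < durationS) {
      if (state == 0L) {
        d <- if (visitRate > 0) rexp(1, visitRate) else durationS + 1
      } else if (state == 1L) {
        d <- rexp(1, 1 / meanDwellS)
      } else {
        d <- rexp(1, 1 / (meanDwellS * preferenceOdds))
      }
      stateSeq <- c(stateSeq, state)
      dwell <- c(dwell, d)
      tAcc <- tAcc + d
      state <- if (state == 0L) sample(1:2, 1L) else 0L
    }
    times <- seq(0, durationS - dtS, by = dtS)
    bounds <- cumsum(dwell)
    stateAt <- stateSeq[findInterval(times, c(0, bounds),
                                     rightmost.closed = FALSE)]
    # batched rejection sampling of uniform positions per zone
    pos <- matrix(NA_real_, length(times), 2L)
    for (st in 0:2) {
      idx <- which(stateAt == st)
      if (!length(idx)) next
      poly <- switch(st + 1L, geometry$tank, geometry$area1, geometry$area2)
      bb <- apply(poly, 2L, range)
      acc <- matrix(NA_real_, 0L, 2L)
      while (nrow(acc) < length(idx)) {
        m <- max(2L * length(idx), 100L)
        cx <- runif(m, bb[1, 1], bb[2, 1])
        cy <- runif(m, bb[1, 2], bb[2, 2])
        ok <- if (st == 0L) {
          !pointInPolygon(cx, cy, geometry$area1) &
            !pointInPolygon(cx, cy, geometry$area2)
        } else {
          pointInPolygon(cx, cy, poly)
        }
        acc <- rbind(acc, cbind(cx[ok], cy[ok]))
      }
      pos[idx, ] <- acc[seq_len(length(idx)), ]
    }
    traj <- Trajectory(data.frame(t_s = times, x_mm = pos[, 1],
                                  y_mm = pos[, 2]),
                       geometry)
    attr(traj, "truth") <- list(preference_odds = preferenceOdds,
                                mean_dwell_s = meanDwellS,
                                visit_rate = visitRate)
    traj
  })
}
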