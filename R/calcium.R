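# Detection and characterization of odor-responsive glomerular regions from
# volumetric calcium recordings: stimulus difference maps, the three
# acceptance criteria (size > 100 px, amplitude above the dataset threshold,
# position inside the glomerular-cluster boundary), AsLS-corrected and
# max-normalized traces, the 12.5% tuning threshold, forskolin
# classification, landmark-normalized positions and Scott's-rule density
# maps.

.frame_window <- function(onset, k) seq.int(onset, onset + k - 1L)

#' Stimulus difference map
#'
#' Computes the voxelwise fluorescence change evoked by one stimulus
#' presentation: the mean of a 3-frame peak window after onset minus the mean
#' of the 5 frames immediately before onset. The peak window is the run of 3
#' consecutive frames, within the interval from onset to stimulus offset plus
#' a decay margin, that maximizes the frame-averaged fluorescence. Negative
#' changes are retained.
#'
#' @param series a [RecordingSeries-class].
#' @param protocol a [StimulusProtocol()] table.
#' @param event row index of the presentation in \code{protocol}.
#' @param peakFrames,baselineFrames window lengths in frames (defaults 3 / 5).
#' @param decayMarginS seconds past stimulus offset still searched for the
#'   peak window (default 10, accommodating slow indicator decay).
#' @return list with \code{map} (3D ΔF array), \code{zproj}
#'   (max-over-z matrix), \code{peak_window} and \code{baseline_window}
#'   (frame indices).
#' @export
differenceMap <- function(series, protocol, event, peakFrames = 3L,
                          baselineFrames = 5L, decayMarginS = 10) {
  stopifnot(event >= 1L, event <= nrow(protocol))
  onset <- protocol$onset_frame[event]
  fp <- framePeriod(series)
  nT <- nFrames(series)
  if (onset - baselineFrames < 1L)
    stop("insufficient frames before stimulus onset")
  if (onset + peakFrames - 1L > nT)
    stop("insufficient frames after stimulus onset")
  lastStart <- min(
    onset + floor((protocol$duration_s[event] + decayMarginS) / fp),
    nT - peakFrames + 1L)
  starts <- seq.int(onset, max(onset, lastStart))
  gmean <- vapply(seq_len(nT), function(t) mean(series@data[, , , t]),
                  numeric(1))
  wmean <- vapply(starts,
                  function(s) mean(gmean[.frame_window(s, peakFrames)]),
                  numeric(1))
  peakW <- .frame_window(starts[which.max(wmean)], peakFrames)
  baseW <- seq.int(onset - baselineFrames, onset - 1L)
  peak <- rowMeans(series@data[, , , peakW, drop = FALSE], dims = 3L)
  base <- rowMeans(series@data[, , , baseW, drop = FALSE], dims = 3L)
  map <- peak - base
  list(map = map, zproj = maxProjectZ(map),
       peak_window = peakW, baseline_window = baseW)
}

#' Per-stimulus difference maps (repeats averaged)
#'
#' Computes the z-projected difference map of every presentation and averages
#' repeats of the same stimulus label.
#'
#' @inheritParams differenceMap
#' @return list with \code{event_maps} (one z-projected matrix per protocol
#'   row) and \code{label_maps} (named list, repeat-averaged per label).
#' @export
stimulusDifferenceMaps <- function(series, protocol, peakFrames = 3L,
                                   baselineFrames = 5L, decayMarginS = 10) {
  eventMaps <- lapply(seq_len(nrow(protocol)), function(e)
    differenceMap(series, protocol, e, peakFrames, baselineFrames,
                  decayMarginS)$zproj)
  labels <- unique(protocol$label)
  labelMaps <- lapply(labels, function(l) {
    maps <- eventMaps[protocol$label == l]
    Reduce(`+`, maps) / length(maps)
  })
  names(labelMaps) <- labels
  list(event_maps = eventMaps, label_maps = labelMaps)
}

#' Extract candidate responsive regions
#'
#' For each stimulus label, supra-noise pixels of the repeat-averaged
#' z-projected difference map are delineated by an Otsu threshold and grouped
#' into 8-connected components; components of 100 pixels or fewer are
#' discarded (criterion i). Candidates found for different stimuli are merged
#' whenever they share pixels, so a region tuned to several stimuli is
#' counted once.
#'
#' @param labelMaps named list of z-projected per-label difference maps
#'   (\code{label_maps} from [stimulusDifferenceMaps()]).
#' @param minArea minimum pixel count, strict (default 100: regions must be
#'   bigger than 100 pixels).
#' @param noiseFloorK supra-noise floor in robust sd units: the per-map
#'   threshold is the larger of the Otsu threshold and
#'   \code{median + noiseFloorK * mad} (default 5). The floor keeps maps
#'   without any response (e.g. the Ringer control) from yielding spurious
#'   noise components.
#' @return list of candidates, each a list with \code{pixels} (linear indices
#'   into the projection matrix), \code{size_px} and \code{centroid}
#'   (\code{c(y, x)} pixel coordinates).
#' @export
extractCandidateRegions <- function(labelMaps, minArea = 100L,
                                    noiseFloorK = 5) {
  stopifnot(length(labelMaps) >= 1L)
  dims <- dim(labelMaps[[1L]])
  comps <- list()
  for (m in labelMaps) {
    if (max(m) <= min(m)) next
    thr <- tryCatch(thresholdOtsu(m), error = function(e) NULL)
    if (is.null(thr)) next
    thr <- max(thr, median(m) + noiseFloorK * mad(m))
    lab <- labelComponents8(m > thr)
    if (max(lab) == 0L) next
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      if (length(px) > minArea) comps[[length(comps) + 1L]] <- px
    }
  }
  if (!length(comps)) return(list())
  # merge candidates across stimuli that share pixels (union-find)
  parent <- seq_along(comps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(comps)) for (j in seq_len(i - 1L)) {
    if (length(intersect(comps[[i]], comps[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(comps), find, integer(1))
  merged <- lapply(unique(roots), function(r)
    sort(unique(unlist(comps[roots == r]))))
  lapply(merged, function(px) {
    yy <- (px - 1L) %% dims[1L] + 1L
    xx <- (px - 1L) %/% dims[1L] + 1L
    list(pixels = px, size_px = length(px),
         centroid = c(y = mean(yy), x = mean(xx)))
  })
}

#' Per-candidate stimulus amplitudes
#'
#' Mean difference-map value over a candidate's pixels, for every
#' presentation in the protocol.
#'
#' @param candidates list from [extractCandidateRegions()].
#' @param eventMaps per-event z-projected maps
#'   (\code{event_maps} from [stimulusDifferenceMaps()]).
#' @return matrix (candidates x events) of raw amplitudes.
#' @export
candidateAmplitudes <- function(candidates, eventMaps) {
  t(vapply(candidates, function(cand)
    vapply(eventMaps, function(m) mean(m[cand$pixels]), numeric(1)),
    numeric(length(eventMaps))))
}

#' Dataset amplitude filter (criterion ii)
#'
#' For each candidate the median of its per-presentation amplitudes is taken;
#' the dataset threshold is the mean of those medians, and a candidate is
#' kept only if its maximal amplitude strictly exceeds the threshold. With
#' identical candidates whose maximum equals their median, the strict
#' inequality removes all of them.
#'
#' @param candidates list from [extractCandidateRegions()].
#' @param amplitudes matrix from [candidateAmplitudes()].
#' @return list with \code{keep} (logical), \code{threshold}, and the
#'   filtered \code{candidates}.
#' @export
amplitudeFilter <- function(candidates, amplitudes) {
  if (!length(candidates)) stop("empty candidate list")
  medians <- apply(amplitudes, 1L, median)
  threshold <- mean(medians)
  keep <- apply(amplitudes, 1L, max) > threshold
  list(keep = keep, threshold = threshold, candidates = candidates[keep])
}

#' Glomerular-cluster boundary filter (criterion iii)
#'
#' Discards regions whose centroid falls outside the manually annotated
#' glomerular-cluster boundary polygon. Centroids on the boundary are kept
#' (closed-polygon convention). Without a polygon the filter passes all
#' regions through with a warning.
#'
#' @param candidates list of candidates (with \code{centroid}).
#' @param boundary polygon matrix (columns x, y, pixel units) or NULL.
#' @return logical keep vector.
#' @export
boundaryFilter <- function(candidates, boundary = NULL) {
  if (is.null(boundary)) {
    warning("no cluster boundary supplied: regions passed through unfiltered")
    return(rep(TRUE, length(candidates)))
  }
  vapply(candidates, function(cand)
    pointInPolygon(cand$centroid["x"], cand$centroid["y"], boundary),
    logical(1))
}

#' Region fluorescence trace
#'
#' Mean raw fluorescence over a region's pixels (averaged over z) per frame.
#'
#' @param series a [RecordingSeries-class].
#' @param pixels linear pixel indices into the (y, x) projection.
#' @return numeric trace of length \code{nFrames(series)}.
#' @export
regionTrace <- function(series, pixels) {
  d <- dim(series@data)
  m <- series@data
  dim(m) <- c(d[1L] * d[2L], d[3L], d[4L])
  zmean <- colMeans(aperm(m[pixels, , , drop = FALSE], c(2L, 1L, 3L)))
  colMeans(zmean)
}

#' Tuning profile of a region (12.5% rule)
#'
#' From a baseline-corrected, max-normalized trace, the response amplitude of
#' each stimulus is the maximum of the trace inside the expected peak
#' interval (onset to offset plus decay margin), averaged across repeats.
#' The tuning set is the set of stimuli whose mean amplitude strictly exceeds
#' 12.5% of the trace maximum. Negative controls (\code{RINGER}) and the
#' positive-control mixture (\code{MIX}) are reported but excluded from the
#' tuning set.
#'
#' @param normTrace normalized trace from [normalizeTrace()].
#' @param protocol stimulus protocol table.
#' @param framePeriodS seconds per frame.
#' @param threshold tuning threshold as a fraction of the trace maximum
#'   (default 0.125).
#' @param decayMarginS seconds past offset included in the peak interval.
#' @param excludeLabels labels never entering the tuning set.
#' @return list with \code{tuning} (character set), \code{amplitudes}
#'   (named, all labels), and \code{responsive} (FALSE for an all-zero trace).
#' @export
tuningProfile <- function(normTrace, protocol, framePeriodS,
                          threshold = 0.125, decayMarginS = 10,
                          excludeLabels = c("RINGER", "MIX")) {
  responsive <- isTRUE(attr(normTrace, "responsive")) || max(normTrace) > 0
  labels <- unique(protocol$label)
  nT <- length(normTrace)
  amp <- vapply(labels, function(l) {
    rows <- which(protocol$label == l)
    mean(vapply(rows, function(e) {
      onset <- protocol$onset_frame[e]
      lastF <- min(nT, onset + floor(
        (protocol$duration_s[e] + decayMarginS) / framePeriodS))
      max(normTrace[seq.int(onset, lastF)])
    }, numeric(1)))
  }, numeric(1))
  names(amp) <- labels
  tun <- if (responsive)
    setdiff(labels[amp > threshold], excludeLabels) else character(0)
  list(tuning = sort(tun), amplitudes = amp, responsive = responsive)
}

#' Forskolin classification
#'
#' A region is forskolin-responsive (\code{"fsk+"}) iff \code{"FSK"} is in
#' its tuning set, marking the cAMP-dependent processing stream.
#'
#' @param tuning character tuning set.
#' @return \code{"fsk+"} or \code{"fsk-"}.
#' @export
classifyFsk <- function(tuning) if ("FSK" %in% tuning) "fsk+" else "fsk-"

#' Normalize a region position to bulb axes
#'
#' Linear interpolation of a centroid between manually defined landmark
#' points: along the medial-lateral axis the lateral edge maps to 0 and the
#' medial edge to 1; along the anterior-posterior axis the anterior edge maps
#' to 0. Centroids outside the landmark span yield values outside
#' \code{[0, 1]} and are flagged, not clipped.
#'
#' @param centroid named numeric \code{c(x = , y = )} in pixel units.
#' @param landmarks list with \code{ml = c(lateral, medial)} x-positions and
#'   \code{ap = c(anterior, posterior)} y-positions.
#' @return list with \code{ml}, \code{ap}, and \code{in_span} flag.
#' @export
normalizePosition <- function(centroid, landmarks) {
  ml <- landmarks$ml
  ap <- landmarks$ap
  if (ml[2] == ml[1] || ap[2] == ap[1])
    stop("coincident landmarks")
  mlv <- unname((centroid[["x"]] - ml[[1]]) / (ml[[2]] - ml[[1]]))
  apv <- unname((centroid[["y"]] - ap[[1]]) / (ap[[2]] - ap[[1]]))
  list(ml = mlv, ap = apv,
       in_span = mlv >= 0 && mlv <= 1 && apv >= 0 && apv <= 1)
}

#' End-to-end analysis of one calcium recording
#'
#' Runs the full response pipeline: per-stimulus difference maps, candidate
#' extraction (size criterion), dataset amplitude filter, optional boundary
#' filter, AsLS baseline correction and normalization of each region trace,
#' SNR sanity check, tuning profiles, forskolin classification, and
#' landmark-normalized positions.
#'
#' @param series a [RecordingSeries-class].
#' @param protocol a [StimulusProtocol()] table.
#' @param landmarks landmark list for [normalizePosition()], or NULL to skip
#'   position normalization.
#' @param boundary glomerular-cluster polygon for [boundaryFilter()], or NULL.
#' @param minArea candidate size threshold (default 100 px, strict).
#' @param tuningThreshold tuning threshold (default 0.125).
#' @param asls list of AsLS parameters (\code{lambda}, \code{p},
#'   \code{nIter}).
#' @param snrMin minimum peak / baseline-sd ratio of the corrected trace
#'   (default 2); regions below are dropped as noise.
#' @param decayMarginS decay margin in seconds (default 10).
#' @return list with \code{regions} (data.frame: id, size_px, centroid,
#'   ml, ap, tuning, fsk, responsive), \code{amplitudes} (normalized, regions
#'   x labels), \code{traces} (list of normalized traces), and
#'   \code{parameters}.
#' @export
analyzeCalciumRecording <- function(series, protocol, landmarks = NULL,
                                    boundary = NULL, minArea = 100L,
                                    tuningThreshold = 0.125,
                                    asls = list(lambda = 1e4, p = 0.01,
                                                nIter = 10L),
                                    snrMin = 2, decayMarginS = 10,
                                    noiseFloorK = 5) {
  maps <- stimulusDifferenceMaps(series, protocol,
                                 decayMarginS = decayMarginS)
  cands <- extractCandidateRegions(maps$label_maps, minArea = minArea,
                                   noiseFloorK = noiseFloorK)
  empty <- list(regions = data.frame(), amplitudes = NULL, traces = list(),
                parameters = list(min_area = minArea,
                                  tuning_threshold = tuningThreshold))
  if (!length(cands)) return(empty)
  ampRaw <- candidateAmplitudes(cands, maps$event_maps)
  flt <- amplitudeFilter(cands, ampRaw)
  cands <- flt$candidates
  if (!length(cands)) return(empty)
  if (!is.null(boundary))
    cands <- cands[boundaryFilter(cands, boundary)]
  if (!length(cands)) return(empty)

  fp <- framePeriod(series)
  rows <- list()
  traces <- list()
  ampNorm <- NULL
  for (i in seq_along(cands)) {
    raw <- regionTrace(series, cands[[i]]$pixels)
    corrected <- baselineCorrectAsls(raw, lambda = asls$lambda, p = asls$p,
                                     nIter = asls$nIter)
    snr <- if (sd(corrected) > 0) max(corrected) / sd(corrected) else 0
    nt <- normalizeTrace(corrected)
    prof <- tuningProfile(nt, protocol, fp, threshold = tuningThreshold,
                          decayMarginS = decayMarginS)
    pos <- if (!is.null(landmarks))
      normalizePosition(cands[[i]]$centroid, landmarks)
    else list(ml = NA_real_, ap = NA_real_, in_span = NA)
    keep <- prof$responsive && length(prof$tuning) > 0L && snr >= snrMin
    if (!keep) next
    traces[[length(traces) + 1L]] <- nt
    ampNorm <- rbind(ampNorm, prof$amplitudes)
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA_integer_, size_px = cands[[i]]$size_px,
      centroid_y = cands[[i]]$centroid[["y"]],
      centroid_x = cands[[i]]$centroid[["x"]],
      ml = pos$ml, ap = pos$ap, in_span = pos$in_span,
      tuning = paste(prof$tuning, collapse = "+"),
      fsk = classifyFsk(prof$tuning), snr = snr)
  }
  if (!length(rows)) return(empty)
  regions <- do.call(rbind, rows)
  regions$id <- seq_len(nrow(regions))
  rownames(ampNorm) <- regions$id
  list(regions = regions, amplitudes = ampNorm, traces = traces,
       parameters = list(min_area = minArea,
                         tuning_threshold = tuningThreshold,
                         snr_min = snrMin, asls = asls,
                         decay_margin_s = decayMarginS,
                         conventions = c(ml = "lateral=0, medial=1",
                                         ap = "anterior=0")))
}

#' Tuning-profile frequency table
#'
#' Percent share of each distinct tuning profile within groups of responsive
#' regions (e.g. stage group x ventral/dorsal half). Percentages within a
#' group sum to 100; empty groups are omitted with a warning.
#'
#' @param profiles character vector of tuning-profile strings (e.g.
#'   \code{"AA"}, \code{"AA+FSK"}).
#' @param groups grouping factor of the same length.
#' @return data.frame with \code{group}, \code{profile}, \code{n},
#'   \code{percent}.
#' @export
profileFrequencyTable <- function(profiles, groups) {
  stopifnot(length(profiles) == length(groups))
  groups <- as.character(groups)
  lv <- unique(groups)
  out <- list()
  for (g in lv) {
    p <- profiles[groups == g]
    if (!length(p)) {
      warning("empty group omitted: ", g)
      next
    }
    tab <- table(p)
    out[[g]] <- data.frame(group = g, profile = names(tab),
                           n = as.integer(tab),
                           percent = 100 * as.integer(tab) / length(p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
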