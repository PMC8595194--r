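# Two-area choice-assay analysis: classification of trajectory samples into
# the two scored areas, visit segmentation, average time per visit within an
# analysis window, the 40-minute exclusion rule, and the paired signed-rank
# preference test.

#' Classify trajectory samples into tank areas
#'
#' @param trajectory a [Trajectory-class].
#' @return integer vector per sample: 1 (area 1), 2 (area 2), 0 (neutral).
#'   Boundary samples (on the wall) resolve to area 1 deterministically.
#' @export
classifyAreas <- function(trajectory) {
  s <- trajectorySamples(trajectory)
  g <- trajectoryGeometry(trajectory)
  in1 <- pointInPolygon(s$x_mm, s$y_mm, g$area1)
  in2 <- pointInPolygon(s$x_mm, s$y_mm, g$area2)
  ifelse(in1, 1L, ifelse(in2, 2L, 0L))
}

#' Segment a trajectory into per-area visits
#'
#' A visit is a maximal contiguous run of samples inside one area; entry and
#' exit are placed at sample boundaries (a sample at time t covers the
#' interval up to the next sample; the final sample covers one median
#' sampling period). Neutral-zone samples belong to no visit, so visit time
#' plus neutral time equals the record duration exactly.
#'
#' @param trajectory a [Trajectory-class].
#' @return list with \code{visits} (data.frame: area, entry_s, exit_s,
#'   duration_s), \code{neutral_s}, and \code{record_s}.
#' @export
segmentVisits <- function(trajectory) {
  s <- trajectorySamples(trajectory)
  if (!nrow(s)) stop("empty trajectory")
  lab <- classifyAreas(trajectory)
  dt <- diff(s$t_s)
  dtLast <- if (length(dt)) median(dt) else 1
  cover <- c(dt, dtLast)              # time covered by each sample
  ends <- c(s$t_s[-1L], s$t_s[nrow(s)] + dtLast)
  r <- rle(lab)
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1L
  runs <- data.frame(area = r$values,
                     entry_s = s$t_s[start_i],
                     exit_s = ends[stop_i])
  runs$duration_s <- vapply(seq_len(nrow(runs)), function(k)
    sum(cover[start_i[k]:stop_i[k]]), numeric(1))
  visits <- runs[runs$area != 0L, , drop = FALSE]
  rownames(visits) <- NULL
  list(visits = visits,
       neutral_s = sum(runs$duration_s[runs$area == 0L]),
       record_s = sum(cover))
}

#' Average time per visit within a window
#'
#' Visit durations are clipped to the analysis window (visits straddling the
#' window edge contribute their inside part, conserving measured time);
#' fully-outside visits are dropped. Areas without any visit return NA.
#'
#' @param visits visit table from [segmentVisits()].
#' @param window numeric length 2, window start and end in seconds.
#' @return named numeric: \code{area1_s}, \code{area2_s} (mean seconds per
#'   visit), plus visit counts as attribute \code{"n_visits"}.
#' @export
averageTimePerVisit <- function(visits, window) {
  if (is.list(visits) && !is.data.frame(visits)) visits <- visits$visits
  stopifnot(length(window) == 2L, window[2] > window[1])
  clip <- pmin(visits$exit_s, window[2]) - pmax(visits$entry_s, window[1])
  keep <- clip > 0
  v <- visits[keep, , drop = FALSE]
  clip <- clip[keep]
  avg <- function(a) {
    d <- clip[v$area == a]
    if (!length(d)) NA_real_ else mean(d)
  }
  out <- c(area1_s = avg(1L), area2_s = avg(2L))
  attr(out, "n_visits") <- c(area1 = sum(v$area == 1L),
                             area2 = sum(v$area == 2L))
  out
}

#' Post-stimulus inclusion rule and analysis window
#'
#' Animals that do not enter either area within the exclusion limit
#' (40 minutes by default, closed bound: entry exactly at the limit is
#' included) after stimulus application are excluded. For included animals
#' the analysis window starts at the first post-stimulus area entry and
#' lasts \code{windowS} (20 minutes).
#'
#' @param trajectory a [Trajectory-class].
#' @param stimulusTimeS stimulus application time (seconds, within record).
#' @param limitS exclusion limit (default 2400 s = 40 min).
#' @param windowS analysis window length (default 1200 s = 20 min).
#' @return list with \code{include} (logical), \code{first_entry_s} (NA if
#'   excluded) and \code{window} (NULL if excluded).
#' @export
applyExclusion <- function(trajectory, stimulusTimeS, limitS = 2400,
                           windowS = 1200) {
  seg <- segmentVisits(trajectory)
  v <- seg$visits
  post <- v[v$entry_s >= stimulusTimeS, , drop = FALSE]
  if (!nrow(post) || (post$entry_s[1L] - stimulusTimeS) > limitS)
    return(list(include = FALSE, first_entry_s = NA_real_, window = NULL))
  t0 <- post$entry_s[1L]
  list(include = TRUE, first_entry_s = t0, window = c(t0, t0 + windowS))
}

#' Paired preference test across animals
#'
#' Wilcoxon signed-rank test on per-animal differences of average time per
#' visit (area 2 minus area 1), two-sided; zero differences are dropped
#' (signed-rank convention) and the exact distribution is used for up to 25
#' non-zero untied differences. Cohort summaries are medians per area.
#'
#' @param statsTable data.frame with one row per animal, columns
#'   \code{area1_s} and \code{area2_s}.
#' @return list with \code{median_area1_s}, \code{median_area2_s},
#'   \code{n}, \code{n_nonzero}, \code{V} (signed-rank statistic),
#'   \code{p_value}, \code{exact}, and \code{note}.
#' @export
pairedPreferenceTest <- function(statsTable) {
  st <- statsTable[complete.cases(statsTable[, c("area1_s", "area2_s")]), ,
                   drop = FALSE]
  n <- nrow(st)
  if (n < 5L) stop("need at least 5 paired observations")
  d <- st$area2_s - st$area1_s
  nz <- d[d != 0]
  med1 <- median(st$area1_s)
  med2 <- median(st$area2_s)
  if (!length(nz))
    return(list(median_area1_s = med1, median_area2_s = med2, n = n,
                n_nonzero = 0L, V = NA_real_, p_value = 1, exact = TRUE,
                note = "all differences zero"))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(st$area2_s, st$area1_s, paired = TRUE,
                       alternative = "two.sided", exact = exact))
  list(median_area1_s = med1, median_area2_s = med2, n = n,
       n_nonzero = length(nz), V = unname(wt$statistic),
       p_value = wt$p.value, exact = exact, note = NA_character_)
}

#' Analyze a behavioral cohort
#'
#' Applies the exclusion rule to every animal, computes per-animal average
#' time per visit inside the individual post-stimulus analysis window, and
#' runs the paired preference test on the included animals.
#'
#' @param trajectories list of [Trajectory-class] objects (one per animal).
#' @param stimulusTimeS stimulus application time (seconds).
#' @param limitS,windowS see [applyExclusion()].
#' @return list with \code{per_animal} (data.frame: animal, included,
#'   first_entry_s, area1_s, area2_s), and \code{test}
#'   ([pairedPreferenceTest()] result over included animals, or NULL when
#'   fewer than 5 remain).
#' @export
analyzeBehaviorCohort <- function(trajectories, stimulusTimeS,
                                  limitS = 2400, windowS = 1200) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    ex <- applyExclusion(tr, stimulusTimeS, limitS, windowS)
    if (!ex$include)
      return(data.frame(animal = i, included = FALSE,
                        first_entry_s = NA_real_,
                        area1_s = NA_real_, area2_s = NA_real_))
    tpv <- averageTimePerVisit(segmentVisits(tr), ex$window)
    data.frame(animal = i, included = TRUE, first_entry_s = ex$first_entry_s,
               area1_s = tpv[["area1_s"]], area2_s = tpv[["area2_s"]])
  })
  perAnimal <- do.call(rbind, rows)
  inc <- perAnimal[perAnimal$included, , drop = FALSE]
  test <- if (sum(complete.cases(inc[, c("area1_s", "area2_s")])) >= 5L)
    pairedPreferenceTest(inc) else NULL
  list(per_animal = perAnimal, test = test)
}
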