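# Projection-field volumetry: relative volume shares of the ventral and
# dorsal MOB projection fields, per-source innervation shares on maximum
# intensity projections, bilateral (left/right) innervation overlap, and
# labeled-pixel profiles along the left-right axis.

#' Maximum intensity projection along z
#'
#' @param x a 3D (y, x, z) array or [BinaryMask-class].
#' @return matrix (y, x); for masks, logical OR over z.
#' @export
maxProjectZ <- function(x) {
  if (is(x, "BinaryMask")) x <- x@data
  apply(x, c(1, 2), max)
}

#' Relative volume shares of the vMOB and dMOB projection fields
#'
#' Computes the percent share of the ventral and dorsal projection-field
#' volumes relative to their sum (both hemispheres pooled). Shares are
#' invariant to voxel-size rescaling since both masks live on one grid.
#'
#' @param vmobMask,dmobMask disjoint [BinaryMask-class] objects on one grid.
#' @param stage optional Nieuwkoop-Faber stage annotation (integer).
#' @return data.frame with \code{vmob_percent}, \code{dmob_percent},
#'   \code{stage}; the two shares sum to 100.
#' @export
volumeShares <- function(vmobMask, dmobMask, stage = NA_integer_) {
  stopifnot(identical(dim(vmobMask@data), dim(dmobMask@data)))
  if (any(vmobMask@data & dmobMask@data))
    stop("vMOB and dMOB masks must be disjoint")
  v <- sum(vmobMask@data)
  d <- sum(dmobMask@data)
  if (v + d == 0L) stop("both masks are empty")
  data.frame(vmob_percent = 100 * v / (v + d),
             dmob_percent = 100 * d / (v + d),
             stage = as.integer(stage))
}

#' Per-source innervation shares on a 2D projection
#'
#' For one compartment's maximum-intensity projection, computes the percent
#' share of pixels carrying signal from each source channel relative to all
#' pixels carrying signal in either channel. Because a pixel can carry both
#' labels, the two shares may sum to more than 100; the union convention is
#' recorded in the result.
#'
#' @param maskA,maskB binarized 2D projections (logical matrices or
#'   [BinaryMask-class] on a single plane) of the two source channels.
#' @return list with \code{percent_a}, \code{percent_b}, pixel counts, and
#'   \code{convention = "union"}.
#' @export
channelShares <- function(maskA, maskB) {
  a <- if (is(maskA, "BinaryMask")) maskA@data else maskA
  b <- if (is(maskB, "BinaryMask")) maskB@data else maskB
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0L) stop("union of the two channel masks is empty")
  list(percent_a = 100 * sum(a) / u,
       percent_b = 100 * sum(b) / u,
       n_a = sum(a), n_b = sum(b), n_union = u,
       convention = "union")
}

#' Bilateral innervation overlap
#'
#' Counts voxels labeled in both the left-origin and right-origin channel
#' masks for each image plane and reports their percent share relative to all
#' voxels carrying any signal: \eqn{100 |L \cap R| / |L \cup R|}.
#'
#' @param maskL,maskR [BinaryMask-class] objects on one grid.
#' @param compartment optional tag ("vmob" or "dmob") carried into the result.
#' @return list with \code{percent}, \code{n_both}, \code{n_any}, a per-plane
#'   data.frame (\code{plane}, \code{n_both}, \code{n_any}) and the tag.
#' @export
bilateralOverlap <- function(maskL, maskR, compartment = NA_character_) {
  stopifnot(identical(dim(maskL@data), dim(maskR@data)))
  both <- maskL@data & maskR@data
  any_ <- maskL@data | maskR@data
  nAny <- sum(any_)
  if (nAny == 0L) stop("no labeled voxels in either channel")
  nz <- dim(both)[3L]
  perPlane <- data.frame(
    plane = seq_len(nz),
    n_both = vapply(seq_len(nz), function(k) sum(both[, , k]), integer(1)),
    n_any = vapply(seq_len(nz), function(k) sum(any_[, , k]), integer(1)))
  list(percent = 100 * sum(both) / nAny,
       n_both = sum(both), n_any = nAny,
       per_plane = perPlane, compartment = compartment)
}

#' Labeled-pixel profile along the left-right axis
#'
#' Counts labeled voxels of the left- and right-origin channels at each
#' normalized position along the left-right (x) axis. In \code{"vmob"} mode
#' the axis runs from the right-edge landmark (0) to the left-edge landmark
#' (1); in \code{"dmob"} mode positions are mirrored about the
#' interhemispheric midline, 0 being the midline and 1 the outer edge.
#'
#' @param maskL,maskR [BinaryMask-class] objects on one grid.
#' @param midlineX x position (voxel index units) of the interhemispheric
#'   midline; required for \code{"dmob"} mode.
#' @param edges numeric length 2, x positions of the outer right and left
#'   edge landmarks; must bracket every labeled voxel.
#' @param mode \code{"vmob"} (edge-to-edge axis) or \code{"dmob"} (mirrored).
#' @param nBins number of equal-width bins across the span (default 100).
#' @return list with \code{position} (bin centers, normalized), per-channel
#'   counts \code{count_left}, \code{count_right}, per-channel \code{peak}
#'   positions (NA, flagged, for an empty channel) and the mode.
#' @export
axisProfile <- function(maskL, maskR, midlineX = NULL, edges,
                        mode = c("vmob", "dmob"), nBins = 100L) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(maskL@data), dim(maskR@data)))
  edges <- sort(as.numeric(edges))
  xs <- function(mask) {
    idx <- which(mask@data)
    if (!length(idx)) return(numeric(0))
    d <- dim(mask@data)
    ((idx - 1L) %/% d[1L]) %% d[2L] + 1L   # x index of each labeled voxel
  }
  xL <- xs(maskL); xR <- xs(maskR)
  allx <- c(xL, xR)
  if (length(allx) && (min(allx) < edges[1] || max(allx) > edges[2]))
    stop("edge landmarks must bracket all labeled voxels")
  norm <- function(x) {
    if (!length(x)) return(numeric(0))
    if (mode == "vmob") {
      (edges[2] - x) / (edges[2] - edges[1])     # 0 = right edge, 1 = left
    } else {
      if (is.null(midlineX)) stop("dmob mode requires midlineX")
      halfspan <- max(edges[2] - midlineX, midlineX - edges[1])
      abs(x - midlineX) / halfspan               # 0 = midline
    }
  }
  breaks <- seq(0, 1, length.out = nBins + 1L)
  mids <- (head(breaks, -1L) + tail(breaks, -1L)) / 2
  binCount <- function(p) {
    if (!length(p)) return(integer(nBins))
    i <- pmin(pmax(findInterval(p, breaks, rightmost.closed = TRUE), 1L), nBins)
    tabulate(i, nbins = nBins)
  }
  cl <- binCount(norm(xL))
  cr <- binCount(norm(xR))
  peak <- function(cnt) if (sum(cnt) == 0L) NA_real_ else mids[which.max(cnt)]
  list(position = mids, count_left = cl, count_right = cr,
       peak_left = peak(cl), peak_right = peak(cr),
       empty_left = sum(cl) == 0L, empty_right = sum(cr) == 0L,
       mode = mode)
}
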