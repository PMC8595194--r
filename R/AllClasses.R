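#' @import methods
#' @importFrom stats median sd mad quantile rnorm runif rexp setNames complete.cases
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

## Spatial arrays are stored with dimensions (y, x, z) and any extra dimension
## (channel, time) last, so that arr[, , k] is one optical plane and
## rowMeans(arr, dims = 3) averages over the trailing dimension. The x axis
## (dimension 2) is the left-right (medial-lateral) axis used for midline and
## axis-profile analyses. Voxel indices are 1-based in R; physical positions
## are voxel centers in micrometers.

# ---------------------------------------------------------------------------
# VoxelStack
# ---------------------------------------------------------------------------

#' Multi-channel 3D fluorescence stack
#'
#' A \code{VoxelStack} holds a multi-channel 3D voxel grid of fluorescence
#' intensities together with its physical voxel spacing. It is the substrate
#' of all volumetric analyses (projection-field volume shares, channel shares,
#' bilateral overlap, axis profiles).
#'
#' @slot data numeric 4D array with dimensions (y, x, z, channel);
#'   non-negative arbitrary fluorescence units.
#' @slot voxelSize named numeric of length 3, micrometers per voxel along
#'   \code{c(y, x, z)}.
#' @slot channels character vector of channel labels, one per channel slab.
#'
#' @seealso [VoxelStack()], [channelData()], [removeAutofluorescence()]
#' @export
setClass("VoxelStack",
  representation(data = "array", voxelSize = "numeric", channels = "character")
)

setValidity("VoxelStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (y, x, z, channel)")
  if (length(object@channels) != d[4L])
    return("number of channel labels must match the 4th array dimension")
  if (anyDuplicated(object@channels))
    return("channel labels must be unique")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (y, x, z)")
  if (any(object@data < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' Construct a VoxelStack
#'
#' @param data 4D numeric array (y, x, z, channel), or a list of 3D arrays
#'   (one per channel) on a common grid.
#' @param voxelSize micrometers per voxel along (y, x, z); a scalar is
#'   recycled to isotropic spacing.
#' @param channels character channel labels.
#' @return A [VoxelStack-class] object.
#' @examples
#' vs <- VoxelStack(array(runif(2 * 4 * 4 * 3), c(4, 4, 3, 2)),
#'                  voxelSize = c(1, 1, 2), channels = c("left", "right"))
#' stackDim(vs)
#' @export
VoxelStack <- function(data, voxelSize = c(1, 1, 1),
                       channels = NULL) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("all channel arrays must share one grid")
    data <- array(unlist(data, use.names = FALSE), c(dims[[1L]], length(data)))
  }
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data), 1L)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[4L]))
  if (length(voxelSize) == 1L)
    voxelSize <- rep(voxelSize, 3L)
  new("VoxelStack", data = data,
      voxelSize = setNames(as.numeric(voxelSize), c("y", "x", "z")),
      channels = as.character(channels))
}

#' @describeIn VoxelStack grid dimensions (y, x, z) of a stack
#' @param x,object a \code{VoxelStack}
#' @export
stackDim <- function(x) dim(x@data)[1:3]

#' Channel accessors
#'
#' \code{channelNames} lists channel labels; \code{channelData} extracts one
#' channel as a 3D (y, x, z) array.
#'
#' @param x a [VoxelStack-class]
#' @param channel channel label or index
#' @return \code{channelNames}: character; \code{channelData}: 3D array.
#' @export
channelNames <- function(x) x@channels

#' @rdname channelNames
#' @export
channelData <- function(x, channel) {
  idx <- if (is.character(channel)) match(channel, x@channels) else channel
  if (is.na(idx) || idx < 1L || idx > length(x@channels))
    stop("unknown channel: ", channel)
  x@data[, , , idx, drop = TRUE]
}

#' Physical voxel spacing in micrometers
#' @param x a [VoxelStack-class] or [BinaryMask-class]
#' @return named numeric length 3 (y, x, z)
#' @export
voxelSize <- function(x) x@voxelSize

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelStack: %d x %d x %d voxels (y,x,z), %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(object@channels, collapse = ", ")))
  cat(sprintf("  voxel size (um): y=%.3g x=%.3g z=%.3g\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

# ---------------------------------------------------------------------------
# BinaryMask
# ---------------------------------------------------------------------------

#' Binary voxel mask
#'
#' A thresholded (or ground-truth) boolean voxel grid on the same spatial grid
#' as its source stack, carrying provenance of how it was produced.
#'
#' @slot data logical 3D array (y, x, z).
#' @slot voxelSize micrometers per voxel (y, x, z).
#' @slot provenance list recording source channel, threshold method and value.
#' @export
setClass("BinaryMask",
  representation(data = "array", voxelSize = "numeric", provenance = "list")
)

setValidity("BinaryMask", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!is.logical(object@data)) return("data must be logical")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  TRUE
})

#' Construct a BinaryMask
#' @param data logical 3D array (y, x, z); 2D input is treated as one plane.
#' @param voxelSize micrometers per voxel (y, x, z); scalar recycled.
#' @param provenance free-form list (channel, method, threshold).
#' @return A [BinaryMask-class]
#' @export
BinaryMask <- function(data, voxelSize = c(1, 1, 1), provenance = list()) {
  if (is.null(dim(data)))
    dim(data) <- c(length(data), 1L, 1L)
  if (length(dim(data)) == 2L)
    dim(data) <- c(dim(data), 1L)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("BinaryMask", data = array(as.logical(data), dim(data)),
      voxelSize = setNames(as.numeric(voxelSize), c("y", "x", "z")),
      provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn BinaryMask number of TRUE voxels
#' @param x a \code{BinaryMask}
#' @export
maskVoxelCount <- function(x) sum(x@data)

#' @describeIn BinaryMask the logical 3D array
#' @export
maskData <- function(x) x@data

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d labeled (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance),
        vapply(object@provenance, function(v) paste(format(v), collapse = ","),
               ""), sep = "=", collapse = "; "), "\n")
})

# ---------------------------------------------------------------------------
# RecordingSeries + StimulusProtocol
# ---------------------------------------------------------------------------

#' Volumetric calcium-imaging time series
#'
#' A 4D fluorescence movie (time series of 3D stacks) with its frame period
#' and voxel spacing; substrate of the odor-response analysis.
#'
#' @slot data numeric 4D array (y, x, z, time), non-negative a.u.
#' @slot framePeriod seconds per volumetric frame (typically 1--2 s).
#' @slot voxelSize micrometers per voxel (y, x, z).
#' @export
setClass("RecordingSeries",
  representation(data = "array", framePeriod = "numeric", voxelSize = "numeric")
)

setValidity("RecordingSeries", function(object) {
  if (length(dim(object@data)) != 4L)
    return("data must be a 4D array (y, x, z, time)")
  if (length(object@framePeriod) != 1L || !is.finite(object@framePeriod) ||
      object@framePeriod <= 0)
    return("framePeriod must be a single positive number")
  if (any(object@data < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' Construct a RecordingSeries
#' @param data 4D numeric array (y, x, z, time)
#' @param framePeriod seconds per frame
#' @param voxelSize micrometers per voxel (y, x, z); scalar recycled
#' @return A [RecordingSeries-class]
#' @export
RecordingSeries <- function(data, framePeriod, voxelSize = c(1, 1, 1)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("RecordingSeries", data = data, framePeriod = as.numeric(framePeriod),
      voxelSize = setNames(as.numeric(voxelSize), c("y", "x", "z")))
}

#' @describeIn RecordingSeries number of volumetric frames
#' @param x a \code{RecordingSeries}
#' @export
nFrames <- function(x) dim(x@data)[4L]

#' @describeIn RecordingSeries seconds per frame
#' @export
framePeriod <- function(x) x@framePeriod

setMethod("show", "RecordingSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "RecordingSeries: %d x %d x %d voxels, %d frames @ %.3g s/frame (%.1f s)\n",
    d[1], d[2], d[3], d[4], object@framePeriod, d[4] * object@framePeriod))
})

#' Stimulus protocol table
#'
#' Builds and validates the ordered stimulus event table of a calcium
#' recording: one row per presentation with label, onset frame, duration and
#' repeat index. Defaults mirror the acquisition protocol: 5-s stimuli at a
#' 60-s inter-stimulus interval, each stimulus repeated at least twice.
#'
#' @param labels character stimulus labels per event (e.g. "AA", "AM", "BA",
#'   "FSK", "MIX", "RINGER").
#' @param onsetFrame integer onset frame per event (1-based).
#' @param durationS stimulus duration in seconds (default 5).
#' @param repeatIndex integer repeat counter per label; computed if missing.
#' @param framePeriod seconds per frame, used only to validate spacing.
#' @return data.frame with columns \code{label}, \code{onset_frame},
#'   \code{duration_s}, \code{repeat_index}.
#' @examples
#' StimulusProtocol(c("AA", "AA"), c(10, 40))
#' @export
StimulusProtocol <- function(labels, onsetFrame, durationS = 5,
                             repeatIndex = NULL, framePeriod = NULL) {
  labels <- as.character(labels)
  onsetFrame <- as.integer(onsetFrame)
  if (length(labels) != length(onsetFrame))
    stop("labels and onsetFrame must have equal length")
  if (any(onsetFrame < 1L)) stop("onset frames must be >= 1")
  durationS <- rep_len(as.numeric(durationS), length(labels))
  if (is.null(repeatIndex))
    repeatIndex <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  o <- order(onsetFrame)
  df <- data.frame(label = labels, onset_frame = onsetFrame,
                   duration_s = durationS,
                   repeat_index = as.integer(repeatIndex))[o, , drop = FALSE]
  if (!is.null(framePeriod)) {
    ends <- df$onset_frame + ceiling(df$duration_s / framePeriod)
    if (any(df$onset_frame[-1L] < head(ends, -1L)))
      stop("stimulus events overlap")
  }
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------
# NeuronTree
# ---------------------------------------------------------------------------

#' Reconstructed neuron as a rooted 3D tree
#'
#' Holds an SWC-style node table: each node has an id, a structure type, a 3D
#' position in micrometers, a radius, and a single parent (soma/root has
#' parent -1). Validity enforces exactly one root and an acyclic, connected
#' parent structure.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}.
#' @seealso [readSWC()], [writeSWC()], [criticalPoints()], [detectTufts()]
#' @export
setClass("NeuronTree", representation(nodes = "data.frame"))

setValidity("NeuronTree", function(object) {
  nd <- object@nodes
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  roots <- nd$id[nd$parent == -1L]
  if (length(roots) != 1L)
    return(sprintf("tree must have exactly one root (found %d)", length(roots)))
  nonroot <- nd$parent != -1L
  if (!all(nd$parent[nonroot] %in% nd$id)) {
    bad <- nd$id[nonroot][!(nd$parent[nonroot] %in% nd$id)][1L]
    return(sprintf("orphan node %d: parent not in tree", bad))
  }
  if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
    return("node positions must be finite")
  # acyclicity + connectivity: every node must reach the root
  idx <- match(nd$parent, nd$id)         # NA for root
  n <- nrow(nd)
  depth <- rep(NA_integer_, n)
  depth[nd$parent == -1L] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ready <- todo[!is.na(depth[idx[todo]])]
    if (!length(ready))
      return(sprintf("cycle detected involving node %d", nd$id[todo[1L]]))
    depth[ready] <- depth[idx[ready]] + 1L
  }
  TRUE
})

#' Construct a NeuronTree
#' @param nodes data.frame with SWC columns
#'   (id, type, x, y, z, radius, parent); positions in micrometers.
#' @return A [NeuronTree-class]
#' @export
NeuronTree <- function(nodes) {
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  new("NeuronTree", nodes = as.data.frame(nodes))
}

#' @describeIn NeuronTree node table accessor
#' @param x a \code{NeuronTree}
#' @export
treeNodes <- function(x) x@nodes

#' @describeIn NeuronTree id of the root (soma) node
#' @export
somaId <- function(x) x@nodes$id[x@nodes$parent == -1L]

setMethod("show", "NeuronTree", function(object) {
  nd <- object@nodes
  nchild <- table(factor(nd$parent, levels = nd$id))
  cat(sprintf(
    "NeuronTree: %d nodes, root id %d, %d endpoints, %d branching points\n",
    nrow(nd), somaId(object),
    sum(nchild == 0L & nd$parent != -1L),
    sum(nchild >= 2L & nd$parent != -1L)))
})

# ---------------------------------------------------------------------------
# Trajectory
# ---------------------------------------------------------------------------

#' Animal trajectory in the two-area choice tank
#'
#' Time-stamped positions together with the tank geometry: two scored areas
#' separated by a dividing wall, plus the shared (neutral) zone.
#'
#' @slot samples data.frame with columns \code{t_s}, \code{x_mm}, \code{y_mm};
#'   time strictly increasing.
#' @slot geometry list with elements \code{tank}, \code{area1}, \code{area2},
#'   each a polygon matrix (columns x, y, mm).
#' @export
setClass("Trajectory",
  representation(samples = "data.frame", geometry = "list"))

setValidity("Trajectory", function(object) {
  s <- object@samples
  if (!all(c("t_s", "x_mm", "y_mm") %in% names(s)))
    return("samples must have columns t_s, x_mm, y_mm")
  if (nrow(s) && any(diff(s$t_s) <= 0))
    return("time must be strictly increasing")
  g <- object@geometry
  if (!all(c("tank", "area1", "area2") %in% names(g)))
    return("geometry must contain tank, area1, area2 polygons")
  TRUE
})

#' Construct a Trajectory
#' @param samples data.frame(t_s, x_mm, y_mm)
#' @param geometry list(tank=, area1=, area2=) of polygon matrices (x, y in mm)
#' @return A [Trajectory-class]
#' @export
Trajectory <- function(samples, geometry) {
  new("Trajectory", samples = as.data.frame(samples), geometry = geometry)
}

#' @describeIn Trajectory sample table accessor
#' @param x a \code{Trajectory}
#' @export
trajectorySamples <- function(x) x@samples

#' @describeIn Trajectory tank geometry accessor
#' @export
trajectoryGeometry <- function(x) x@geometry

setMethod("show", "Trajectory", function(object) {
  s <- object@samples
  cat(sprintf("Trajectory: %d samples, %.1f s record\n", nrow(s),
              if (nrow(s)) diff(range(s$t_s)) else 0))
})

#' Default two-area choice tank geometry
#'
#' A 1-liter rectangular tank (200 x 100 mm footprint by default) split along
#' half its length by a dividing wall: area 1 (left) and area 2 (right) sit on
#' either side of the wall in the back half; the front half is the shared
#' neutral zone through which the animal moves freely.
#'
#' @param width,height tank footprint in mm.
#' @param wallFraction fraction of the tank height occupied by the divided
#'   areas (default 0.5, a wall along approx. half the length).
#' @return geometry list usable with [Trajectory()].
#' @export
defaultTankGeometry <- function(width = 200, height = 100,
                                wallFraction = 0.5) {
  rect <- function(x0, y0, x1, y1)
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  yw <- height * (1 - wallFraction)
  list(tank = rect(0, 0, width, height),
       area1 = rect(0, yw, width / 2, height),
       area2 = rect(width / 2, yw, width, height))
}
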