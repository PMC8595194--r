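# Small image-processing primitives with pinned conventions: per-plane 2D
# median filtering (square window, reflection padding, even windows centered
# by the lower-left convention) and 8-connectivity connected components.

#' Subtract the autofluorescence (blue) channel
#'
#' Tissue autofluorescence is estimated by a blue-wavelength channel recorded
#' without any blue-emitting dye; it is removed from a signal channel by
#' voxelwise subtraction clamped at zero. Other channels are untouched.
#'
#' @param stack a [VoxelStack-class].
#' @param signalChannel channel to correct (label or index).
#' @param blueChannel autofluorescence reference channel.
#' @return A [VoxelStack-class] with the signal channel replaced by
#'   \code{pmax(signal - blue, 0)}.
#' @export
removeAutofluorescence <- function(stack, signalChannel, blueChannel) {
  sig <- channelData(stack, signalChannel)
  blue <- channelData(stack, blueChannel)
  out <- stack
  idx <- if (is.character(signalChannel))
    match(signalChannel, stack@channels) else signalChannel
  out@data[, , , idx] <- pmax(sig - blue, 0)
  validObject(out)
  out
}

.median_filter_plane <- function(m, size) {
  size <- as.integer(size)
  if (size < 1L) stop("filter size must be >= 1")
  if (size == 1L) return(m)
  off <- (0:(size - 1L)) - size %/% 2L   # even sizes: lower-left centered
  ny <- nrow(m); nx <- ncol(m)
  reflect <- function(i, n) {            # reflect-without-repeat padding
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  k <- size * size
  npix <- ny * nx
  stackv <- matrix(0, npix, k)
  j <- 0L
  for (dy in off) for (dx in off) {
    j <- j + 1L
    stackv[, j] <- m[reflect(seq_len(ny) + dy, ny),
                     reflect(seq_len(nx) + dx, nx)]
  }
  # per-pixel median without an R-level loop: radix-order the window values
  # grouped by pixel, then pick the middle order statistic(s)
  o <- order(rep.int(seq_len(npix), k), as.vector(stackv))
  sorted <- matrix(as.vector(stackv)[o], nrow = k)
  med <- if (k %% 2L == 1L) sorted[(k + 1L) %/% 2L, ]
         else (sorted[k %/% 2L, ] + sorted[k %/% 2L + 1L, ]) / 2
  matrix(med, ny, nx)
}

#' Per-plane 2D median filter
#'
#' Applies a square-window median filter of the given pixel size to every
#' z-plane of every channel, the artifact-removal step preceding Huang
#' binarization in the bilateral-overlap analysis. Edge handling is by
#' reflection; even window sizes are centered by the lower-left convention
#' (offsets \code{-size/2 .. size/2 - 1}).
#'
#' @param x a [VoxelStack-class], a 3D (y, x, z) array, or a matrix.
#' @param size window side length in pixels (>= 1).
#' @return object of the same kind as \code{x}, filtered.
#' @export
medianFilter2D <- function(x, size) {
  if (is(x, "VoxelStack")) {
    out <- x
    for (c in seq_along(x@channels))
      for (k in seq_len(dim(x@data)[3L]))
        out@data[, , k, c] <- .median_filter_plane(x@data[, , k, c], size)
    return(out)
  }
  if (is.matrix(x)) return(.median_filter_plane(x, size))
  if (length(dim(x)) == 3L) {
    for (k in seq_len(dim(x)[3L]))
      x[, , k] <- .median_filter_plane(x[, , k], size)
    return(x)
  }
  stop("x must be a VoxelStack, 3D array or matrix")
}

#' Connected components with 8-connectivity
#'
#' Labels connected regions of a logical matrix using 8-neighborhood
#' connectivity (edge- and corner-adjacent pixels connect), as used for
#' candidate-region extraction on z-projected difference maps.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components are
#'   labeled 1..k in order of first (column-major) occurrence.
#' @export
labelComponents8 <- function(mask) {
  stopifnot(is.matrix(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nextLab <- 0L
  idxAll <- which(mask)
  for (start in idxAll) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      cy <- (cur - 1L) %% ny + 1L
      cx <- (cur - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        yy <- cy + dy; xx <- cx + dx
        ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
        if (!any(ok)) next
        nb <- (xx[ok] - 1L) * ny + yy[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nextLab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Point-in-polygon test
#'
#' Ray-casting test with a closed-boundary convention: points on a polygon
#' edge or vertex count as inside (so a region whose centroid lies exactly on
#' the glomerular-cluster boundary is kept).
#'
#' @param x,y point coordinates (vectorized).
#' @param poly polygon matrix, columns x and y, vertices in order.
#' @return logical vector.
#' @export
pointInPolygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  onEdge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- px[j[k]]; y1 <- py[j[k]]; x2 <- px[k]; y2 <- py[k]
    cross <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    # collinear and within segment bounding box -> on edge
    d <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    onSeg <- abs(d) < 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    onEdge <- onEdge | onSeg
  }
  inside | onEdge
}

# Run expr with a private RNG stream; the caller's global RNG state is
# untouched. All generators route their randomness through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
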