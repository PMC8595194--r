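# 3D convex hull volume by incremental insertion. Small point sets only
# (tuft clusters hold tens of critical points), so an O(n^2) incremental
# construction with explicit horizon handling is ample.

.cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

.face_make <- function(tri, pts, interior) {
  a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
  nrm <- .cross3(b - a, c - a)
  d <- sum(nrm * a)
  if (sum(nrm * interior) > d) {    # flip so the normal points outward
    tri <- tri[c(1L, 3L, 2L)]
    nrm <- -nrm
    d <- sum(nrm * pts[tri[1], ])
  }
  list(v = tri, n = nrm, d = d, len = sqrt(sum(nrm^2)))
}

#' Convex hull volume of a 3D point set
#'
#' Volume of the convex hull of the given points, used to estimate the
#' volume of a dendritic tuft from its branching- and endpoints. Fewer than
#' four points, or a degenerate (collinear/coplanar) set, yields volume 0
#' with \code{degenerate = TRUE}.
#'
#' @param pts numeric matrix (n x 3) of positions in micrometers.
#' @return list with \code{volume} (cubic micrometers) and \code{degenerate}.
#' @examples
#' convexHullVolume(rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10),
#'                        c(10,10,0), c(10,0,10), c(0,10,10), c(10,10,10)))
#' @export
convexHullVolume <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  stopifnot(ncol(pts) == 3L)
  n <- nrow(pts)
  degen <- list(volume = 0, degenerate = TRUE)
  if (n < 4L) return(degen)
  scale <- max(apply(pts, 2L, function(cc) diff(range(cc))))
  if (scale == 0) return(degen)
  tol <- 1e-9 * scale

  # initial simplex: two extreme points, the point maximizing triangle area,
  # then the point maximizing tetrahedron height
  i1 <- which.min(pts[, 1L])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= tol) return(degen)
  e1 <- pts[i2, ] - pts[i1, ]
  area2 <- apply(pts, 1L, function(p) sum(.cross3(e1, p - pts[i1, ])^2))
  i3 <- which.max(area2)
  if (sqrt(area2[i3]) <= tol * sqrt(sum(e1^2))) return(degen)   # collinear
  nrm <- .cross3(e1, pts[i3, ] - pts[i1, ])
  heights <- abs(as.numeric(pts %*% nrm) - sum(nrm * pts[i1, ])) /
    sqrt(sum(nrm^2))
  i4 <- which.max(heights)
  if (heights[i4] <= tol) return(degen)                          # coplanar

  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[simplex, ])
  faces <- lapply(list(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                       simplex[c(1, 3, 4)], simplex[c(2, 3, 4)]),
                  .face_make, pts = pts, interior = interior)

  for (p in setdiff(seq_len(n), simplex)) {
    pv <- pts[p, ]
    distAbove <- vapply(faces, function(f)
      (sum(f$n * pv) - f$d) / f$len, numeric(1))
    vis <- which(distAbove > tol)
    if (!length(vis)) next
    # horizon = undirected edges appearing exactly once among visible faces
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(sort(f$v[c(1, 2)]), sort(f$v[c(2, 3)]), sort(f$v[c(3, 1)]))))
    key <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[-vis]
    for (k in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <-
        .face_make(c(horizon[k, ], p), pts, interior)
  }

  vol <- sum(vapply(faces, function(f)
    sum(pts[f$v[1L], ] * .cross3(pts[f$v[2L], ], pts[f$v[3L], ])),
    numeric(1))) / 6
  list(volume = abs(vol), degenerate = FALSE)
}
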