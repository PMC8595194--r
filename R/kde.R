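# Gaussian kernel density estimation with Scott's-rule bandwidths for the
# spatial maps of responsive regions along the normalized medial-lateral and
# anterior-posterior bulb axes.

#' Scott's-rule bandwidth
#'
#' \eqn{h_j = \hat\sigma_j \, n^{-1/(d+4)}} per axis, the bandwidth rule used
#' for all spatial density estimates.
#'
#' @param x numeric vector (one axis of the data).
#' @param n sample count (defaults to \code{length(x)}).
#' @param d dimensionality of the estimate (2 for joint maps, 1 for margins).
#' @return bandwidth (standard deviation of the Gaussian kernel).
#' @export
scottBandwidth <- function(x, n = length(x), d = 1L) {
  sd(x) * n^(-1 / (d + 4))
}

.kde1d <- function(x, grid, h) {
  # product-free 1D Gaussian KDE evaluated on a grid
  sapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = h)))
}

#' Spatial density map of responsive regions
#'
#' Estimates the density of region positions over the normalized
#' (medial-lateral, anterior-posterior) unit square with a diagonal-bandwidth
#' Gaussian product kernel, bandwidths by Scott's rule per axis (d = 2).
#' The map is scaled by the number of contributing regions, so its integral
#' over the grid equals the region count (up to quadrature error). Margins
#' are estimated as independent 1D KDEs (d = 1). If an axis has zero
#' variance (collinear positions), the joint map is dropped and only the 1D
#' margins of the non-degenerate axes are returned, with a warning.
#'
#' @param positions data.frame or matrix with columns \code{ml} and \code{ap}
#'   (normalized coordinates, typically in \code{[0, 1]}).
#' @param group label carried into the result (e.g. "fsk+" or "fsk-").
#' @param gridN grid resolution per axis (default 64).
#' @return list with \code{ml}, \code{ap} (grid axes), \code{density}
#'   (matrix ml x ap, scaled by n, or NULL on fallback), marginal estimates
#'   \code{margin_ml}, \code{margin_ap}, \code{bandwidth}, \code{peak}
#'   (ml/ap of the joint-density argmax), \code{n}, \code{group}.
#' @export
densityEstimate <- function(positions, group = NA_character_, gridN = 64L) {
  pos <- as.data.frame(positions)
  if (!all(c("ml", "ap") %in% names(pos)))
    names(pos)[1:2] <- c("ml", "ap")
  pos <- pos[complete.cases(pos[, c("ml", "ap")]), , drop = FALSE]
  n <- nrow(pos)
  if (n < 2L) stop("need at least 2 positions per group")
  lim <- function(v) range(c(0, 1, v))
  gml <- seq(lim(pos$ml)[1], lim(pos$ml)[2], length.out = gridN)
  gap <- seq(lim(pos$ap)[1], lim(pos$ap)[2], length.out = gridN)
  hml2 <- scottBandwidth(pos$ml, n, d = 2L)
  hap2 <- scottBandwidth(pos$ap, n, d = 2L)
  degenerate <- hml2 == 0 || hap2 == 0 || !is.finite(hml2) || !is.finite(hap2)
  dens <- NULL
  peak <- c(ml = NA_real_, ap = NA_real_)
  if (degenerate) {
    warning("singular covariance: falling back to per-axis 1D estimates")
  } else {
    kml <- outer(gml, pos$ml, function(g, x) stats::dnorm(g, x, hml2))
    kap <- outer(gap, pos$ap, function(g, x) stats::dnorm(g, x, hap2))
    # product kernel: density(g1,g2) = 1/n sum_i K(g1 - ml_i) K(g2 - ap_i),
    # then scaled by the region count n (so the grid integral ~ n)
    dens <- tcrossprod(kml, kap)
    am <- arrayInd(which.max(dens), dim(dens))
    peak <- c(ml = gml[am[1]], ap = gap[am[2]])
  }
  h1ml <- scottBandwidth(pos$ml, n, d = 1L)
  h1ap <- scottBandwidth(pos$ap, n, d = 1L)
  marg <- function(v, grid, h) {
    if (h == 0 || !is.finite(h)) return(rep(NA_real_, length(grid)))
    .kde1d(v, grid, h) * n
  }
  list(ml = gml, ap = gap, density = dens,
       margin_ml = marg(pos$ml, gml, h1ml),
       margin_ap = marg(pos$ap, gap, h1ap),
       bandwidth = c(ml = hml2, ap = hap2),
       peak = peak, n = n, group = group)
}
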