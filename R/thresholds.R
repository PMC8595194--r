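# Global image thresholding on 256-bin histograms. Gray levels are bin
# centers; a pixel is foreground iff its value is strictly greater than the
# returned threshold. Tie rule: the smallest optimizing threshold wins.

#' Image histogram for thresholding
#'
#' Builds the histogram all thresholding methods operate on. Integer-valued
#' images in \code{[0, 255]} get one bin per gray level (8-bit parity);
#' everything else gets \code{nBins} equal-width bins over the observed range.
#'
#' @param x numeric vector or array of intensities.
#' @param nBins number of bins for non-8-bit data (default 256).
#' @return list with \code{mids} (bin-center gray levels) and \code{counts}.
#' @export
imageHistogram <- function(x, nBins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities")
  r <- range(x)
  if (all(x == round(x)) && r[1] >= 0 && r[2] <= 255) {
    mids <- 0:255
    counts <- tabulate(x + 1L, nbins = 256L)
  } else {
    if (r[1] == r[2])
      return(list(mids = r[1], counts = length(x)))
    breaks <- seq(r[1], r[2], length.out = nBins + 1L)
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                nBins)
    counts <- tabulate(idx, nbins = nBins)
    mids <- (head(breaks, -1L) + tail(breaks, -1L)) / 2
  }
  list(mids = mids, counts = counts)
}

.as_histogram <- function(x, nBins = 256L) {
  if (is.list(x) && all(c("mids", "counts") %in% names(x))) x
  else imageHistogram(x, nBins)
}

.check_histogram <- function(h) {
  keep <- h$counts > 0
  if (sum(keep) < 2L)
    stop("degenerate histogram: fewer than 2 distinct gray levels")
  h
}

#' Maximum-entropy threshold (Kapur-Sahoo-Wong)
#'
#' Selects the threshold maximizing the sum of the Shannon entropies of the
#' background and foreground sub-histograms, the criterion used to binarize
#' projection-field images before computing channel shares.
#'
#' @param x intensities (vector/array) or a histogram from [imageHistogram()].
#' @param nBins bins used when \code{x} is raw intensities.
#' @return threshold on the gray-level scale (a bin center); pixels strictly
#'   above it are foreground.
#' @examples
#' thresholdMaxEntropy(c(rep(10, 50), rep(200, 50)))
#' @export
thresholdMaxEntropy <- function(x, nBins = 256L) {
  h <- .check_histogram(.as_histogram(x, nBins))
  p <- h$counts / sum(h$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  A <- cumsum(plogp)
  n <- length(p)
  t <- seq_len(n - 1L)
  valid <- P[t] > 0 & P[t] < 1
  Hb <- -A[t] / P[t] + log(P[t])
  Hw <- -(A[n] - A[t]) / (1 - P[t]) + log1p(-P[t])
  phi <- Hb + Hw
  phi[!valid] <- -Inf
  h$mids[t[which.max(phi)]]
}

#' Huang fuzzy threshold (minimum fuzziness)
#'
#' Selects the threshold minimizing total image fuzziness
#' \eqn{\sum_g S(\mu_t(g)) h(g)} with membership
#' \eqn{\mu_t(g) = 1 / (1 + |g - m_{class}(t)| / C)} (class-mean attraction,
#' \eqn{C} = full gray-level range) and \eqn{S} the Shannon entropy function.
#' This is the binarization used for the bilateral-overlap analysis.
#'
#' @inheritParams thresholdMaxEntropy
#' @return threshold gray level (bin center); foreground is strictly above.
#' @export
thresholdHuang <- function(x, nBins = 256L) {
  h <- .check_histogram(.as_histogram(x, nBins))
  g <- h$mids
  w <- h$counts
  n <- length(g)
  C <- g[n] - g[1]
  P <- cumsum(w)
  S1 <- cumsum(w * g)
  t <- seq_len(n - 1L)
  valid <- P[t] > 0 & P[t] < P[n]
  shannon <- function(mu) {
    s <- numeric(length(mu))
    ok <- mu > 0 & mu < 1
    s[ok] <- -mu[ok] * log(mu[ok]) - (1 - mu[ok]) * log1p(-mu[ok])
    s
  }
  E <- rep(Inf, n - 1L)
  for (ti in t[valid]) {
    mu0 <- S1[ti] / P[ti]
    mu1 <- (S1[n] - S1[ti]) / (P[n] - P[ti])
    lo <- seq_len(ti)
    hi <- seq.int(ti + 1L, n)
    mem <- c(1 / (1 + abs(g[lo] - mu0) / C), 1 / (1 + abs(g[hi] - mu1) / C))
    E[ti] <- sum(w * shannon(mem))
  }
  g[t[which.min(E)]]
}

#' Otsu threshold
#'
#' Maximizes between-class variance on the shared 256-bin histogram. Used to
#' delineate supra-noise pixels on calcium difference maps before the
#' connected-component / 100-pixel candidate rule.
#'
#' @inheritParams thresholdMaxEntropy
#' @return threshold gray level (bin center); foreground is strictly above.
#' @export
thresholdOtsu <- function(x, nBins = 256L) {
  h <- .check_histogram(.as_histogram(x, nBins))
  p <- h$counts / sum(h$counts)
  g <- h$mids
  P <- cumsum(p)
  M <- cumsum(p * g)
  mt <- M[length(M)]
  t <- seq_len(length(g) - 1L)
  valid <- P[t] > 0 & P[t] < 1
  sb <- (mt * P[t] - M[t])^2 / (P[t] * (1 - P[t]))
  sb[!valid] <- -Inf
  g[t[which.max(sb)]]
}

#' Binarize one channel of a stack
#'
#' Applies a global threshold method to a single channel and returns the
#' resulting [BinaryMask-class] with full provenance.
#'
#' @param stack a [VoxelStack-class].
#' @param channel channel label or index.
#' @param method one of \code{"max_entropy"}, \code{"huang"}, \code{"otsu"}.
#' @param nBins histogram bins (default 256).
#' @return A [BinaryMask-class]; voxels strictly above the threshold are TRUE.
#' @export
binarizeChannel <- function(stack, channel,
                            method = c("max_entropy", "huang", "otsu"),
                            nBins = 256L) {
  method <- match.arg(method)
  arr <- channelData(stack, channel)
  thr <- switch(method,
    max_entropy = thresholdMaxEntropy(arr, nBins),
    huang = thresholdHuang(arr, nBins),
    otsu = thresholdOtsu(arr, nBins))
  BinaryMask(arr > thr, voxelSize = voxelSize(stack),
             provenance = list(channel = channel, method = method,
                               threshold = thr))
}
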