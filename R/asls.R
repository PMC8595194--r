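# Asymmetric least squares (AsLS) baseline correction: an iteratively
# reweighted Whittaker smoother. The baseline z minimizes
#   sum_i w_i (y_i - z_i)^2 + lambda * sum_i (D2 z)_i^2
# with asymmetric weights w_i = p where y_i > z_i and 1 - p otherwise, so the
# smooth baseline hugs the lower envelope of the trace and transient calcium
# peaks are preserved in the residual y - z.

#' AsLS baseline correction of a fluorescence trace
#'
#' @param trace numeric fluorescence time series (finite values).
#' @param lambda smoothness penalty on the second difference of the baseline
#'   (dimensionless, per-sample scale; default 1e4).
#' @param p asymmetry parameter in (0, 1); small values (default 0.01) make
#'   points above the baseline nearly weightless so peaks do not drag it up.
#' @param nIter number of reweighting iterations (default 10).
#' @param returnBaseline if TRUE return a list with both the corrected trace
#'   and the baseline; otherwise just the corrected trace \code{y - z}.
#' @return numeric corrected trace (or list, see \code{returnBaseline}).
#' @examples
#' y <- 0.05 * (1:200) + ifelse(1:200 %in% 80:90, 10, 0)
#' cor <- baselineCorrectAsls(y)
#' @export
baselineCorrectAsls <- function(trace, lambda = 1e4, p = 0.01, nIter = 10L,
                                returnBaseline = FALSE) {
  y <- as.numeric(trace)
  n <- length(y)
  if (n <= 3L) stop("trace must be longer than 3 samples")
  if (any(!is.finite(y))) stop("trace contains non-finite samples")
  stopifnot(lambda > 0, p > 0, p < 1)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(nIter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  if (returnBaseline) list(corrected = y - z, baseline = z) else y - z
}

#' Normalize a trace to the unit interval
#'
#' Rescales a baseline-corrected trace so that baseline maps to 0 and the
#' maximum to 1. Negative excursions are clamped at 0 so normalized response
#' amplitudes lie in \code{[0, 1]}. A constant (all-zero) trace is returned
#' unchanged with attribute \code{responsive = FALSE}.
#'
#' @param trace baseline-corrected numeric trace.
#' @return numeric trace in \code{[0, 1]} (attribute \code{responsive}).
#' @export
normalizeTrace <- function(trace) {
  m <- max(trace)
  if (m <= 0) {
    out <- rep(0, length(trace))
    attr(out, "responsive") <- FALSE
    return(out)
  }
  out <- pmax(trace, 0) / m
  attr(out, "responsive") <- TRUE
  out
}
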