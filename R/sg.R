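#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing in a symmetric sliding window of
#' odd length `window = 2w + 1`: each interior point is replaced by the
#' degree-`order` fit evaluated at the window center; the first/last `w`
#' points come from the first/last full window with the polynomial evaluated
#' at the off-center positions.  Delegates to [signal::sgolayfilt()], whose
#' projection matrix implements exactly this endpoint scheme.
#'
#' @param x a [spectrum1d].
#' @param window odd window length `>= 3`.  An even request is adjusted
#'   upward to the next odd length with a warning.
#' @param order polynomial degree, `< window` (default 3: the common
#'   spectroscopy choice, preserving peak heights better than quadratic).
#' @return smoothed [spectrum1d], same length and grid.
#' @examples
#' s <- spectrum1d(0:20, (0:20)^2)
#' max(abs(sg_smooth(s, 7, 2)$intensity - s$intensity))  # ~1e-12: quadratics
#' @export
sg_smooth <- function(x, window, order = 3L) {
  stopifnot(is_spectrum1d(x))
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    warning("sg_smooth: even window ", window, " adjusted to ", window + 1L)
    window <- window + 1L
  }
  if (window < 3L) stop_validation("window must be >= 3")
  if (window > length(x$axis))
    stop_validation("window (", window, ") exceeds signal length (",
                    length(x$axis), ")")
  if (order >= window) stop_validation("order must be < window")
  y <- signal::sgolayfilt(x$intensity, p = order, n = window)
  spectrum1d(x$axis, y, label = x$label)
}
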