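## Empirical mode decomposition by envelope-mean sifting.
##
## Each intrinsic mode function (IMF) must (i) have extrema and zero-crossing
## counts equal or differing by one and (ii) a locally zero mean of the upper
## and lower cubic-spline envelopes.  Sifting subtracts the envelope mean
## until those conditions (or a Cauchy criterion on successive iterates) are
## met; accepted IMFs are subtracted from the running residual.  Extraction
## is therefore exact: sum(IMFs) + residual == input by construction.

#' Sifting configuration for [emd_decompose()]
#'
#' @param max_imfs cap on the number of IMFs (`Inf` = unlimited).
#' @param sd_threshold Cauchy stabilization threshold for the sift,
#'   `sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold` (classical 0.2).
#'   A candidate is accepted once it is both stabilized and passes the IMF
#'   conditions ([is_imf] at `imf_tol`).
#' @param imf_tol envelope-mean tolerance certifying the IMF conditions
#'   (default 0.1).
#' @param max_sift_iter cap on sift iterations per IMF; hitting it accepts
#'   the candidate uncertified (flagged and logged).
#' @param min_extrema stop extracting once the residual has fewer than this
#'   many interior extrema (default 2: near-monotone trend).
#' @param energy_tol stop once the residual L2 norm falls below
#'   `energy_tol * ||input||` (negligible residue).
#' @return validated list of class `emd_params`.
#' @export
emd_params <- function(max_imfs = Inf, sd_threshold = 0.2, imf_tol = 0.1,
                       max_sift_iter = 64L, min_extrema = 2L,
                       energy_tol = 0.05) {
  if (sd_threshold <= 0) stop_validation("sd_threshold must be > 0")
  if (imf_tol <= 0) stop_validation("imf_tol must be > 0")
  if (max_sift_iter < 1L) stop_validation("max_sift_iter must be >= 1")
  if (min_extrema < 2L) stop_validation("min_extrema must be >= 2")
  structure(list(max_imfs = max_imfs, sd_threshold = sd_threshold,
                 imf_tol = imf_tol,
                 max_sift_iter = as.integer(max_sift_iter),
                 min_extrema = as.integer(min_extrema),
                 energy_tol = energy_tol),
            class = "emd_params")
}

## Interior extrema as strict sign changes of the first difference; plateaus
## count once at their midpoint.  Returns 1-based indices.
find_extrema <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  nz <- which(s != 0)
  maxima <- integer(); minima <- integer()
  if (length(nz) >= 2L) {
    for (i in seq_len(length(nz) - 1L)) {
      a <- nz[i]; b <- nz[i + 1L]
      if (s[a] > 0 && s[b] < 0) maxima <- c(maxima, (a + b + 1L) %/% 2L)
      if (s[a] < 0 && s[b] > 0) minima <- c(minima, (a + b + 1L) %/% 2L)
    }
  }
  list(maxima = maxima, minima = minima)
}

## Strict sign changes; exact zeros count once.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

monotone_residual_condition <- function(msg = "too few extrema for envelopes") {
  structure(class = c("vmdenoise_monotone_residual", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

## Cubic-spline envelope through extrema, with the two extrema nearest each
## end mirrored outside the domain to tame endpoint swings.
spline_envelope <- function(idx, val, n) {
  ord <- order(idx)
  idx <- idx[ord]; val <- val[ord]
  m <- length(idx)
  xs <- c(2 - rev(idx[1:2]), idx, 2 * n - rev(idx[(m - 1L):m]))
  ys <- c(rev(val[1:2]), val, rev(val[(m - 1L):m]))
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}

#' Upper/lower cubic-spline envelopes and their mean
#'
#' @param x numeric vector with at least two interior maxima and two interior
#'   minima; otherwise a condition of class `vmdenoise_monotone_residual` is
#'   signalled (the caller treats the input as a monotone residual).
#' @return list with `m` (envelope mean), `upper`, `lower`.
#' @export
envelope_mean <- function(x) {
  x <- as.numeric(x)
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L)
    stop(monotone_residual_condition())
  n <- length(x)
  upper <- spline_envelope(ex$maxima, x[ex$maxima], n)
  lower <- spline_envelope(ex$minima, x[ex$minima], n)
  list(m = (upper + lower) / 2, upper = upper, lower = lower)
}

#' Test the two defining conditions of an intrinsic mode function
#'
#' TRUE iff the numbers of interior extrema and zero-crossings are equal or
#' differ by one, and the envelope-mean magnitude on the interior 80% of
#' samples is at most `tol` times the signal amplitude.
#'
#' @param x numeric vector, length >= 8.
#' @param tol relative envelope-mean tolerance (default 0.05).
#' @return logical flag.
#' @export
is_imf <- function(x, tol = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop_validation("is_imf needs length >= 8")
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  if (abs(n_ext - count_zero_crossings(x)) > 1L) return(FALSE)
  m <- tryCatch(envelope_mean(x)$m, vmdenoise_monotone_residual = function(e) NULL)
  if (is.null(m)) return(FALSE)
  n <- length(x)
  interior <- seq.int(ceiling(n * 0.1), floor(n * 0.9))
  amp <- max(abs(x[interior]))
  if (amp == 0) return(FALSE)
  max(abs(m[interior])) <= tol * amp
}

#' Decompose a spectrum into IMFs plus a residual by EMD
#'
#' IMFs are returned in extraction order (descending oscillation frequency);
#' the residual is the remaining near-monotone trend.  Additivity is exact:
#' `rowSums(modes) + residual` equals the input at machine precision.
#' IMFs whose sift hit `max_sift_iter` without satisfying the IMF conditions
#' are reported via a message and flagged in `params$sift_capped`.
#'
#' @param x a [spectrum1d].
#' @param p an [emd_params].
#' @return a [decomposition] with `method = "emd"`.
#' @export
emd_decompose <- function(x, p = emd_params()) {
  stopifnot(is_spectrum1d(x))
  if (!inherits(p, "emd_params")) stop_validation("p must be an emd_params")
  f <- x$intensity
  n <- length(f)
  input_norm <- sqrt(sum(f^2))
  r <- f
  imfs <- list()
  capped <- logical()

  repeat {
    if (length(imfs) >= p$max_imfs) break
    if (sqrt(sum(r^2)) <= p$energy_tol * input_norm) break
    ex <- find_extrema(r)
    if (length(ex$maxima) + length(ex$minima) < p$min_extrema) break
    h <- r
    hit_cap <- TRUE
    exhausted <- TRUE
    for (s in seq_len(p$max_sift_iter)) {
      em <- tryCatch(envelope_mean(h),
                     vmdenoise_monotone_residual = function(e) NULL)
      if (is.null(em)) {
        # candidate lost its extrema mid-sift; accept uncertified
        exhausted <- FALSE
        break
      }
      h_new <- h - em$m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), 1e-300)
      h <- h_new
      if (sd_crit < p$sd_threshold && is_imf(h, p$imf_tol)) {
        hit_cap <- FALSE
        exhausted <- FALSE
        break
      }
    }
    if (hit_cap && exhausted)
      message("emd_decompose: sift cap reached for IMF ", length(imfs) + 1L)
    imfs[[length(imfs) + 1L]] <- h
    capped <- c(capped, hit_cap)
    r <- r - h
  }

  if (!length(imfs)) {
    modes <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    modes <- do.call(cbind, imfs)
  }
  decomposition("emd", modes, residual = r, dx = x$dx,
                params = c(unclass(p), list(sift_capped = capped)))
}
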