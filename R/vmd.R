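## Variational mode decomposition.
##
## The signal is decomposed into K narrowband modes u_k with adaptive center
## frequencies omega_k by minimizing the total mode bandwidth subject to
## (approximate) reconstruction.  The saddle point of the augmented Lagrangian
## is found by ADMM, with every sub-problem solved in closed form in the
## Fourier domain on the nonnegative-frequency (analytic) half spectrum:
##
##   u_k  <- (f_hat - sum_{i != k} u_i + lambda/2) / (1 + 2*alpha*(w - w_k)^2)
##   w_k  <- sum_w w |u_k(w)|^2 / sum_w |u_k(w)|^2          (w >= 0)
##   lam  <- lam + tau * (f_hat - sum_k u_k)
##
## until the summed relative update norm drops below `tol`.

#' Solver configuration for [vmd_decompose()]
#'
#' @param K number of modes (>= 1).
#' @param alpha bandwidth penalty (> 0); larger alpha yields narrower modes.
#' @param tau dual ascent step (>= 0).  `tau = 0` relaxes exact
#'   reconstruction, the standard noise-robust choice for denoising.
#' @param tol convergence threshold on the summed relative update norm,
#'   in (0, 1).
#' @param max_iter iteration cap.
#' @param init center-frequency initialization: `"uniform"` spreads omega_k
#'   evenly over (0, 0.5), `"zero"` starts all at 0, `"random"` draws
#'   uniformly (seeded).
#' @param dc pin the first center frequency to 0 (for signals with a strong
#'   baseline).
#' @param mirror reflect half the signal length at each end before the
#'   transform and crop afterwards, suppressing endpoint effects.
#' @param seed seed for `init = "random"`.
#' @return validated parameter list of class `vmd_params`.
#' @export
vmd_params <- function(K, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 500L,
                       init = c("uniform", "zero", "random"), dc = FALSE,
                       mirror = TRUE, seed = NULL) {
  init <- match.arg(init)
  if (K < 1L) stop_validation("K must be >= 1")
  if (alpha <= 0) stop_validation("alpha must be > 0")
  if (tau < 0) stop_validation("tau must be >= 0")
  if (tol <= 0 || tol >= 1) stop_validation("tol must be in (0, 1)")
  if (max_iter < 1L) stop_validation("max_iter must be >= 1")
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), init = init, dc = dc,
                 mirror = mirror, seed = seed),
            class = "vmd_params")
}

dft_freqs <- function(T) {
  j <- 0:(T - 1L)
  ((j + T %/% 2L) %% T - T %/% 2L) / T
}

#' Decompose a spectrum into band-limited modes by VMD
#'
#' @param x a [spectrum1d].
#' @param p a [vmd_params] (or `K` plus `...` shortcuts).
#' @return list with `decomposition` (modes in ascending center-frequency
#'   order, frequencies in cycles/sample; `$params$center_freq_axis` gives
#'   them in cycles per axis unit) and `state` (final Fourier-domain
#'   iterates: `u_hat`, `omega`, `lambda_hat`, `iter`, `delta`).
#' @examples
#' t <- seq(0, 1 - 1e-3, by = 1e-3)
#' s <- spectrum1d(t, cos(2 * pi * 2 * t) + 0.25 * cos(2 * pi * 20 * t))
#' d <- vmd_decompose(s, vmd_params(K = 2))$decomposition
#' d$center_freq / s$dx   # ~ 2 and 20 cycles per axis unit
#' @export
vmd_decompose <- function(x, p) {
  stopifnot(is_spectrum1d(x))
  if (!inherits(p, "vmd_params")) stop_validation("p must be a vmd_params")
  f <- x$intensity
  N <- length(f)
  if (p$K > N %/% 2L)
    stop_validation("K = ", p$K, " exceeds the number of resolvable bands ",
                    "floor(N/2) = ", N %/% 2L)

  if (p$mirror) {
    el <- N %/% 2L; er <- N - el
    fm <- c(rev(f[seq_len(el)]), f, rev(f[(N - er + 1L):N]))
  } else {
    el <- 0L
    fm <- f
  }
  T <- length(fm)
  freqs <- dft_freqs(T)
  pos <- which(freqs >= 0)
  fp <- freqs[pos]
  f_hat <- stats::fft(fm)[pos]

  K <- p$K
  u <- matrix(0 + 0i, length(pos), K)
  omega <- switch(p$init,
    uniform = 0.5 * (seq_len(K) - 0.5) / K,
    zero = rep(0, K),
    random = with_seed(p$seed, sort(stats::runif(K, 0, 0.5)))
  )
  if (p$dc) omega[1] <- 0
  lambda <- complex(length(pos))
  deltas <- numeric(p$max_iter)
  resid_norms <- numeric(p$max_iter)
  iter <- 0L
  delta <- Inf

  for (it in seq_len(p$max_iter)) {
    iter <- it
    u_prev <- u
    usum <- rowSums(u)
    for (k in seq_len(K)) {
      usum <- usum - u[, k]
      u[, k] <- (f_hat - usum + lambda / 2) /
        (1 + 2 * p$alpha * (fp - omega[k])^2)
      if (!(p$dc && k == 1L)) {
        pw <- Mod(u[, k])^2
        tot <- sum(pw)
        if (tot > 0) omega[k] <- sum(fp * pw) / tot
      }
      usum <- usum + u[, k]
    }
    if (p$tau > 0) lambda <- lambda + p$tau * (f_hat - usum)
    resid_norms[it] <- sqrt(sum(Mod(f_hat - usum)^2))
    dk <- colSums(Mod(u - u_prev)^2) / pmax(colSums(Mod(u_prev)^2), 1e-300)
    delta <- sum(dk)
    deltas[it] <- delta
    if (delta < p$tol) break
    mode_energy <- sum(Mod(u)^2)
    if (!is.finite(mode_energy) || mode_energy > 100 * sum(Mod(f_hat)^2))
      stop_validation("VMD diverged (mode energy blew up); reduce alpha (",
                      p$alpha, ") or tau (", p$tau, ")")
  }

  ord <- order(omega)
  modes <- matrix(0, N, K)
  for (j in seq_len(K)) {
    k <- ord[j]
    full <- complex(T)
    full[pos] <- u[, k]
    neg <- which(freqs < 0)
    jj <- (neg - 1L)              # 0-based bins
    mirror_bins <- (T - jj) %% T  # conjugate partners
    full[neg] <- Conj(full[mirror_bins + 1L])
    ut <- Re(stats::fft(full, inverse = TRUE)) / T
    modes[, j] <- ut[(el + 1L):(el + N)]
  }
  omega_sorted <- pmin(pmax(omega[ord], 0), 0.5)

  dec <- decomposition("vmd", modes, center_freq = omega_sorted, dx = x$dx,
                       params = c(unclass(p)[c("K", "alpha", "tau", "tol",
                                               "max_iter", "init", "dc",
                                               "mirror")],
                                  list(center_freq_axis = omega_sorted / x$dx)))
  state <- structure(list(u_hat = u[, ord, drop = FALSE],
                          omega = omega_sorted,
                          lambda_hat = lambda, iter = iter, delta = delta,
                          freqs = fp,
                          resid_norms = resid_norms[seq_len(iter)]),
                     class = "vmd_state")
  list(decomposition = dec, state = state)
}

#' Reconstruct a spectrum from selected VMD modes
#'
#' @param d a `vmd` [decomposition].
#' @param kept nonempty vector of 1-based mode indices to sum.
#' @param axis axis values of the source grid (defaults to sample index
#'   scaled by `d$dx`).
#' @param label label for the reconstructed spectrum.
#' @return a [spectrum1d] holding the element-wise sum of the kept modes.
#' @export
vmd_reconstruct <- function(d, kept, axis = NULL, label = "vmd reconstruction") {
  stopifnot(inherits(d, "decomposition"))
  if (d$method != "vmd") stop_validation("decomposition method must be vmd")
  kept <- as.integer(kept)
  if (!length(kept)) stop_validation("kept must be nonempty")
  if (any(kept < 1L | kept > n_modes(d)))
    stop_validation("mode index out of range 1..", n_modes(d))
  if (is.null(axis)) axis <- d$dx * (seq_len(d$source_len) - 1L)
  spectrum1d(axis, rowSums(d$modes[, kept, drop = FALSE]), label = label)
}

#' Suggest a mode count for VMD
#'
#' Increases K until the highest center frequency exceeds `nyquist_frac` of
#' the Nyquist frequency (0.5 cycles/sample), i.e. until the top mode is
#' chasing broadband noise.
#'
#' @param x a [spectrum1d].
#' @param nyquist_frac fraction of Nyquist (default 0.5).
#' @param max_k search cap.
#' @param ... forwarded to [vmd_params()].
#' @return suggested K (integer).
#' @export
vmd_suggest_k <- function(x, nyquist_frac = 0.5, max_k = 10L, ...) {
  for (K in seq_len(max_k)) {
    d <- vmd_decompose(x, vmd_params(K = K, ...))$decomposition
    if (max(d$center_freq) > nyquist_frac * 0.5) return(K)
  }
  max_k
}
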