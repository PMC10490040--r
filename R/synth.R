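## Synthetic benchmark signals.
##
## Benchmark 1: three cosines of well-separated frequencies plus white noise.
## Benchmark 2: a Raman-like spectrum -- three Lorentzian peaks of differing
## widths/heights over a slowly varying sqrt background, plus white Gaussian
## noise injected at a stated SNR in dB.

#' Evaluate a three-parameter Lorentzian A / ((a*x - b)^2 + c)
#'
#' The generalized Lorentzian used by the second benchmark; `a` scales the
#' axis (sharper peak for larger `a`), the peak sits at `x = b/a` with height
#' `A/c`.
#'
#' @param x axis values.
#' @param A,a,b,c real constants, `c > 0`.
#' @return numeric vector.
#' @export
lorentz_component <- function(x, A, a, b, c) {
  if (c <= 0) stop_validation("lorentzian needs c > 0")
  A / ((a * x - b)^2 + c)
}

signal1_evaluators <- function() {
  list(
    f1 = function(x) cos(2 * pi * 2 * x) - 3,
    f2 = function(x) cos(2 * pi * 20 * x) / 4,
    f3 = function(x) cos(2 * pi * 50 * x) / 6
  )
}

signal2_evaluators <- function() {
  list(
    f4 = function(x) lorentz_component(x, 2, 5, 70, 3),
    f5 = function(x) lorentz_component(x, 5, 1, 3, 3),
    f6 = function(x) lorentz_component(x, 4, 1, -2, 4),
    f7 = function(x) {
      if (any(x < 0))
        stop_validation("background sqrt component undefined for x < 0")
      0.03 * sqrt(x)
    }
  )
}

#' Add white Gaussian noise at a stated SNR in dB
#'
#' The noise standard deviation is calibrated in closed form,
#' `sigma = sqrt(sum(f^2) / (s * 10^(snr_db/10)))` with `s` the number of
#' samples, so that the expected realized SNR
#' `10*log10(sum(f^2)/sum(noise^2))` equals `snr_db`.
#'
#' @param clean a [spectrum1d] with nonzero energy.
#' @param snr_db target SNR in dB (finite).
#' @param seed integer seed; the draw is a pure function of (clean, snr_db,
#'   seed).
#' @return a noised [spectrum1d] on the same grid.
#' @export
add_noise_db <- function(clean, snr_db, seed) {
  stopifnot(is_spectrum1d(clean))
  if (!is.finite(snr_db)) stop_validation("snr_db must be finite")
  energy <- sum(clean$intensity^2)
  if (energy == 0)
    stop_validation("SNR undefined for an all-zero signal")
  s <- length(clean$axis)
  sigma <- sqrt(energy / (s * 10^(snr_db / 10)))
  noise <- with_seed(seed, stats::rnorm(s, 0, sigma))
  spectrum1d(clean$axis, clean$intensity + noise,
             label = paste0(clean$label, " + noise(", snr_db, " dB)"))
}

finalize_signal <- function(x, comps, noise_mode, noise_level, seed, label) {
  vals <- lapply(comps, function(f) f(x))
  clean <- Reduce(`+`, vals)
  clean_sp <- spectrum1d(x, clean, label = label)
  if (noise_mode == "none") {
    noised_sp <- clean_sp
    noise <- rep(0, length(x))
  } else if (noise_mode == "sigma") {
    if (noise_level <= 0) stop_validation("noise sigma must be > 0")
    noise <- with_seed(seed, stats::rnorm(length(x), 0, noise_level))
    noised_sp <- spectrum1d(x, clean + noise, label = paste0(label, " (noised)"))
  } else {
    noised_sp <- add_noise_db(clean_sp, noise_level, seed)
    noise <- noised_sp$intensity - clean
  }
  components <- c(
    lapply(seq_along(vals), function(i)
      spectrum1d(x, vals[[i]], label = names(comps)[i])),
    list(spectrum1d(x, noise, label = "noise"))
  )
  names(components) <- c(names(comps), "noise")
  list(clean = clean_sp, noised = noised_sp, components = components)
}

#' Generate the first benchmark signal (three cosines + noise)
#'
#' `f1 = cos(2*pi*2x) - 3`, `f2 = cos(2*pi*20x)/4`, `f3 = cos(2*pi*50x)/6`
#' on `x in [0, 1)` so the tones complete 2, 20 and 50 cycles.  White Gaussian
#' noise of standard deviation `sigma` is added.
#'
#' @param seed integer seed for the noise draw.
#' @param n number of samples (default 1000).
#' @param sigma noise standard deviation (default 0.05).
#' @param x0,dx grid origin and spacing (default `[0, 1)` grid).
#' @return list with `clean`, `noised` ([spectrum1d]) and `components`
#'   (named list `f1`, `f2`, `f3`, `noise`).
#' @export
gen_signal1 <- function(seed = 1L, n = 1000L, sigma = 0.05,
                        x0 = 0, dx = 1 / n) {
  if (n < 8L) stop_validation("n_points must be >= 8")
  if (dx <= 0) stop_validation("dx must be > 0")
  x <- x0 + dx * (seq_len(n) - 1L)
  finalize_signal(x, signal1_evaluators(), "sigma", sigma, seed,
                  "synthetic signal 1")
}

#' Generate the second benchmark signal (Lorentzian peaks + background)
#'
#' `f4 = 2/((5x-70)^2+3)`, `f5 = 5/((x-3)^2+3)`, `f6 = 4/((x+2)^2+4)` and the
#' background `f7 = 0.03*sqrt(x)` on 551 points with spacing 0.1 starting at
#' 0, emulating a Raman spectrum of peaks with differing widths and heights.
#' White Gaussian noise is injected at `snr_db` (default 20 dB) via
#' [add_noise_db()].
#'
#' @param seed integer seed for the noise draw.
#' @param n number of samples (default 551).
#' @param dx grid spacing (default 0.1).
#' @param x0 grid origin (default 0; negative origins are rejected by the
#'   sqrt background).
#' @param snr_db noise level as SNR in dB (default 20).
#' @return list with `clean`, `noised` and `components` (`f4`..`f7`, `noise`).
#' @export
gen_signal2 <- function(seed = 1L, n = 551L, dx = 0.1, x0 = 0, snr_db = 20) {
  if (n < 8L) stop_validation("n_points must be >= 8")
  if (dx <= 0) stop_validation("dx must be > 0")
  x <- x0 + dx * (seq_len(n) - 1L)
  finalize_signal(x, signal2_evaluators(), "snr_db", snr_db, seed,
                  "synthetic signal 2")
}
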