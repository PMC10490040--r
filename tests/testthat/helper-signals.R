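# fixtures built in code: unit grid, tones, two-tone test signal

unit_grid <- function(n = 1000L) seq(0, 1 - 1 / n, length.out = n)

tone <- function(t, cycles, amp = 1) amp * cos(2 * pi * cycles * t)

two_tone_spectrum <- function(n = 1000L) {
  t <- unit_grid(n)
  spectrum1d(t, tone(t, 2) + tone(t, 20, 0.25), label = "two-tone")
}

interior <- function(n, frac = 0.8) {
  lo <- ceiling(n * (1 - frac) / 2)
  seq.int(lo, n - lo)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

with_seed_rnorm <- function(seed, n, ...) {
  set.seed(seed)
  rnorm(n, ...)
}
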