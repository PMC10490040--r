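test_that("VMD separates a well-spaced two-tone signal", {
  s <- two_tone_spectrum()
  out <- vmd_decompose(s, vmd_params(K = 2))
  d <- out$decomposition
  centers_axis <- d$center_freq / s$dx
  expect_lt(abs(centers_axis[1] - 2), 0.5)
  expect_lt(abs(centers_axis[2] - 20), 0.5)

  t <- s$axis
  idx <- interior(length(t))
  expect_gt(cor(d$modes[idx, 1], tone(t, 2)[idx]), 0.99)
  expect_gt(cor(d$modes[idx, 2], tone(t, 20, 0.25)[idx]), 0.99)

  # near-completeness of the converged decomposition
  rec <- vmd_reconstruct(d, 1:2, axis = t)
  expect_lt(rel_l2(rec$intensity, s$intensity), 0.01)
  # keeping only the low mode recovers the slow tone
  low <- vmd_reconstruct(d, 1, axis = t)
  expect_gt(cor(low$intensity[idx], tone(t, 2)[idx]), 0.99)
})

test_that("a constant signal is a DC fixed point", {
  s <- spectrum1d(1:64, rep(2.5, 64))
  out <- vmd_decompose(s, vmd_params(K = 1, dc = TRUE))
  expect_equal(out$decomposition$center_freq, 0)
  expect_lt(max(abs(out$decomposition$modes[, 1] - 2.5)), 1e-8)
})

test_that("VMD recovers the three cosines of the clean first benchmark", {
  s1 <- gen_signal1(seed = 1)
  d <- vmd_decompose(s1$clean, vmd_params(K = 3))$decomposition
  idx <- interior(length(s1$clean$axis))
  for (k in 1:3) {
    comp <- s1$components[[k]]$intensity
    expect_gt(cor(d$modes[idx, k], comp[idx]), 0.95)
  }
})

test_that("center frequencies are ascending within [0, 0.5]", {
  for (seed in 1:3) {
    x <- spectrum1d(1:256, with_seed_rnorm(seed, 256))
    d <- vmd_decompose(x, vmd_params(K = 4))$decomposition
    expect_false(is.unsorted(d$center_freq))
    expect_true(all(d$center_freq >= 0 & d$center_freq <= 0.5))
  }
})

test_that("random initializations agree after frequency sorting", {
  s <- two_tone_spectrum(512)
  d1 <- vmd_decompose(s, vmd_params(K = 2, init = "random", seed = 1))
  d2 <- vmd_decompose(s, vmd_params(K = 2, init = "random", seed = 99))
  expect_lt(max(abs(d1$decomposition$center_freq -
                    d2$decomposition$center_freq)), 1e-3)
  expect_lt(rel_l2(d1$decomposition$modes[, 1],
                   d2$decomposition$modes[, 1]), 0.01)
})

test_that("doubling alpha never widens a mode's spectral bandwidth", {
  s <- two_tone_spectrum(512)
  bw <- function(alpha) {
    st <- vmd_decompose(s, vmd_params(K = 2, alpha = alpha))$state
    expect_lt(st$iter, 500L)  # property is only claimed at convergence
    vapply(1:2, function(k) {
      pw <- Mod(st$u_hat[, k])^2
      mu <- sum(st$freqs * pw) / sum(pw)
      sum((st$freqs - mu)^2 * pw) / sum(pw)
    }, 0)
  }
  b1 <- bw(500); b2 <- bw(1000); b3 <- bw(2000)
  expect_true(all(b2 <= b1 + 1e-12))
  expect_true(all(b3 <= b2 + 1e-12))
})

test_that("dual ascent drives the reconstruction residual down", {
  s <- two_tone_spectrum(512)
  st <- vmd_decompose(s, vmd_params(K = 2, tau = 0.5))$state
  tail_norms <- utils::tail(st$resid_norms, 10)
  expect_true(all(diff(tail_norms) <= 1e-9))
})

test_that("an overdriven dual ascent is reported as divergence", {
  s <- two_tone_spectrum(512)
  expect_error(vmd_decompose(s, vmd_params(K = 2, tau = 20)),
               "reduce alpha")
})

test_that("infeasible mode counts and indices are rejected", {
  s <- spectrum1d(1:16, rnorm(16))
  expect_error(vmd_decompose(s, vmd_params(K = 9)), "resolvable bands")
  d <- vmd_decompose(two_tone_spectrum(128), vmd_params(K = 2))$decomposition
  expect_error(vmd_reconstruct(d, 3), "out of range")
  expect_error(vmd_reconstruct(d, integer()), "nonempty")
})
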