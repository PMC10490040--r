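test_that("SG smoothing reproduces polynomials up to its order exactly", {
  x <- seq(-3, 3, length.out = 41)
  for (deg in 0:3) {
    y <- x^deg
    s <- spectrum1d(x, y)
    out <- sg_smooth(s, window = 9, order = 3)
    expect_lt(max(abs(out$intensity - y)), 1e-10)  # endpoints included
  }
  # quadratic through a window-7 quadratic fit
  s2 <- spectrum1d(1:30, (1:30)^2)
  expect_lt(max(abs(sg_smooth(s2, 7, 2)$intensity - (1:30)^2)), 1e-8)
})

test_that("the 5-point quadratic impulse response solves the normal equations", {
  # independent oracle: projection row of the LS fit evaluated at center
  k <- -2:2
  X <- cbind(1, k, k^2)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  weights <- H[3, ]
  expect_equal(weights, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)

  n <- 21
  impulse <- numeric(n); impulse[11] <- 1
  out <- sg_smooth(spectrum1d(1:n, impulse), window = 5, order = 2)
  expect_equal(out$intensity[11], 17 / 35, tolerance = 1e-12)
  expect_equal(out$intensity[9:13], weights, tolerance = 1e-12)
})

test_that("SG smoothing is linear and preserves constants", {
  n <- 64
  a <- with_seed_rnorm(1, n); b <- with_seed_rnorm(2, n)
  sg <- function(v) sg_smooth(spectrum1d(1:n, v), 11, 3)$intensity
  expect_lt(max(abs(sg(2 * a + 3 * b) - (2 * sg(a) + 3 * sg(b)))), 1e-10)
  expect_lt(max(abs(sg(rep(7, n)) - 7)), 1e-10)
})

test_that("even SG windows are bumped to the next odd length with a warning", {
  s <- spectrum1d(1:64, with_seed_rnorm(3, 64))
  expect_warning(out16 <- sg_smooth(s, 16), "adjusted to 17")
  out17 <- sg_smooth(s, 17)
  expect_identical(out16$intensity, out17$intensity)
  expect_error(sg_smooth(s, 65), "exceeds signal length")
  expect_error(sg_smooth(s, 7, order = 7), "order must be")
})

test_that("the wavelet transform is a perfect-reconstruction filter bank", {
  for (w in c("haar", "db4", "sym8")) {
    for (n in c(512L, 551L, 1000L)) {
      x <- with_seed_rnorm(n, n)
      for (lev in seq_len(dwt_max_level(n, w))) {
        dec <- dwt_forward(x, w, lev)
        expect_lt(max(abs(dwt_inverse(dec) - x)), 1e-10)
      }
    }
  }
})

test_that("zero-threshold denoising is an identity", {
  s <- gen_signal2(seed = 5)$noised
  for (w in c("haar", "db4", "sym8")) {
    out <- dwt_denoise(s, wavelet = w, threshold = 0)
    expect_lt(max(abs(out$denoised$intensity - s$intensity)), 1e-10)
  }
})

test_that("thresholding shrinks coefficients by definition", {
  lam <- 1.3
  expect_equal(threshold_coefficients(3 * lam, lam, "soft"), 2 * lam)
  expect_equal(threshold_coefficients(lam / 2, lam, "soft"), 0)
  expect_equal(threshold_coefficients(-3 * lam, lam, "soft"), -2 * lam)
  expect_equal(threshold_coefficients(3 * lam, lam, "hard"), 3 * lam)
  expect_equal(threshold_coefficients(lam / 2, lam, "hard"), 0)

  cf <- with_seed_rnorm(4, 200)
  hard <- threshold_coefficients(cf, 0.5, "hard")
  soft <- threshold_coefficients(cf, 0.5, "soft")
  expect_lte(sum(hard^2), sum(cf^2))
  expect_lt(sum(soft^2), sum(cf^2))   # strict: some |c| exceed lambda
})

test_that("universal soft thresholding suppresses white noise", {
  ratios <- vapply(1:10, function(seed) {
    x <- spectrum1d(1:1024, 5 + with_seed_rnorm(seed, 1024, sd = 0.3))
    out <- dwt_denoise(x)
    expect_gte(out$report$level, 4L)
    var(out$denoised$intensity) / var(x$intensity - 5)
  }, 0)
  expect_lt(mean(ratios), 0.25)
})

test_that("inadmissible levels are rejected with the maximum stated", {
  expect_error(dwt_forward(rnorm(64), "sym8", 5), "maximum is 2")
  expect_error(dwt_denoise(spectrum1d(1:8, rnorm(8)), wavelet = "sym8"),
               "too short")
  expect_error(dwt_forward(rnorm(64), "nope", 1), "unknown wavelet")
})
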