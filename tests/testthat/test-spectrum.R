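test_that("spectrum1d rejects each constructed violation distinctly", {
  expect_error(spectrum1d(1:8, 1:7), "differ in length")
  expect_error(spectrum1d(1:7, 1:7), "at least 8 points")
  expect_error(spectrum1d(1:8, c(1:7, NaN)), "NA/NaN")
  expect_error(spectrum1d(c(1:7, 7.5), 1:8), "non-uniform")
  expect_error(spectrum1d(c(1:7, 7), 1:8), "strictly increasing")
  expect_error(spectrum1d(c(1:7, Inf), 1:8), "NA/NaN/Inf")
})

test_that("spectrum1d records the grid spacing", {
  s <- spectrum1d(seq(100, 107) * 2.9, rnorm(8))
  expect_equal(s$dx, 2.9)
  expect_equal(length(s), 8L)
})

test_that("read_spectrum parses two-column text and normalizes axis order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(0:7, 1:8, sep = ","), path)
  s <- read_spectrum(path)
  expect_s3_class(s, "spectrum1d")
  expect_equal(s$axis, as.numeric(0:7))
  expect_equal(s$intensity, as.numeric(1:8))

  # descending twin reads to the same spectrum
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(7:0, 8:1, sep = ","), path2)
  expect_message(s2 <- read_spectrum(path2), "reversing")
  expect_equal(s2$axis, s$axis)
  expect_equal(s2$intensity, s$intensity)
})

test_that("read_spectrum honors skip_header and names bad lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", paste(0:7, 1:8, sep = ",")), path)
  expect_error(read_spectrum(path), "line 1")
  expect_equal(length(read_spectrum(path, skip_header = TRUE)), 8L)

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(0:3, 1:4, sep = ","), "4,oops",
               paste(5:7, 6:8, sep = ",")), path3)
  expect_error(read_spectrum(path3), "line 5")
  expect_error(read_spectrum("no/such/file.csv", ),
               class = "vmdenoise_io_error")
})

test_that("spectrum write/read round-trips to 1e-10", {
  s <- spectrum1d(seq(0, 5.5, by = 0.5), rnorm(12), label = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, skip_header = TRUE)
  expect_lt(max(abs(s2$intensity - s$intensity)), 1e-10)
  expect_lt(max(abs(s2$axis - s$axis)), 1e-10)
})

test_that("decompositions round-trip through CSV + JSON sidecar", {
  modes <- cbind(sin(1:16), cos(1:16))
  d <- decomposition("vmd", modes, center_freq = c(0.05, 0.2), dx = 0.5,
                     params = list(K = 2, alpha = 2000))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decomposition(d, path)
  expect_true(file.exists(paste0(path, ".json")))
  d2 <- read_decomposition(path)
  expect_equal(d2$method, "vmd")
  expect_equal(d2$center_freq, d$center_freq)
  expect_lt(max(abs(d2$modes - d$modes)), 1e-10)
  expect_equal(colnames(d2$modes), c("u1", "u2"))

  e <- decomposition("emd", cbind(rnorm(12), rnorm(12), rnorm(12)),
                     residual = rnorm(12), dx = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_decomposition(e, path2)
  header <- readLines(path2, n = 1L)
  expect_equal(header, "imf1,imf2,imf3,residual")
  e2 <- read_decomposition(path2)
  expect_lt(max(abs(e2$residual - e$residual)), 1e-10)
  expect_lt(max(abs(e2$modes - e$modes)), 1e-10)
})

test_that("decomposition and denoise_result enforce their invariants", {
  expect_error(decomposition("vmd", cbind(1:8), center_freq = c(0.2, 0.3)),
               "one center frequency per mode")
  expect_error(decomposition("vmd", cbind(1:8, 2:9), center_freq = c(0.3, 0.1)),
               "ascending")
  expect_error(decomposition("vmd", cbind(1:8), center_freq = 0.7), "0, 0.5")
  expect_error(decomposition("emd", cbind(1:8)), "residual")

  s <- spectrum1d(1:8, rnorm(8))
  expect_error(denoise_result(s, kept = c(1, 2), removed = c(2, 3)),
               "overlap")
  expect_error(denoise_result(s, kept = c(1, 3), removed = 4L),
               "partition")
  ok <- denoise_result(s, kept = c(1, 2), removed = 3L)
  expect_equal(sort(c(ok$kept, ok$removed)), 1:3)
})
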