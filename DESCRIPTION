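Package: vmdenoise
Title: Variational Mode Decomposition Denoising for One-Dimensional Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Denoising of uniformly sampled one-dimensional spectra (Raman and
    Raman-like signals) by variational mode decomposition (VMD): the spectrum
    is split into band-limited modes by an alternating-direction method of
    multipliers in the Fourier domain, high-frequency noise modes are removed,
    and the remaining modes are reconstructed.  Empirical mode decomposition
    (EMD), Savitzky-Golay smoothing and discrete-wavelet thresholding are
    provided as comparators, together with a signal-to-noise-ratio benchmark
    harness, seeded synthetic-signal generators (sums of cosines, and
    Lorentzian peaks over a slowly varying background with additive white
    Gaussian noise at a stated SNR), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
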