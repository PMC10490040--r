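# vmdenoise

Denoising of uniformly sampled one-dimensional spectra — Raman and
Raman-like signals — by **variational mode decomposition (VMD)**, with
empirical mode decomposition (EMD), Savitzky–Golay (SG) smoothing and
discrete-wavelet thresholding (DWT) as comparators, plus seeded synthetic
benchmarks and an SNR-based comparison harness.  It is aimed at
spectroscopists and chemometricians who need a transparent, scriptable
preprocessing step with a quantitative way to choose between denoisers.

## The method

VMD decomposes a signal into $K$ narrowband modes $u_k$ with adaptive
center frequencies $\omega_k$ by minimizing total mode bandwidth subject to
approximate reconstruction.  The ADMM iteration runs in the Fourier domain:

$$\hat u_k \leftarrow \frac{\hat f - \sum_{i\neq k}\hat u_i + \hat\lambda/2}{1 + 2\alpha(\omega-\omega_k)^2},\qquad
\omega_k \leftarrow \frac{\sum_{\omega\ge 0}\omega|\hat u_k|^2}{\sum_{\omega\ge 0}|\hat u_k|^2},\qquad
\hat\lambda \leftarrow \hat\lambda + \tau\big(\hat f - \sum_k\hat u_k\big).$$

High-frequency modes carry the noise; summing the low-frequency modes gives
the denoised spectrum.  Results are scored as
$\mathrm{SNR} = 10\log_{10}\left(\sum_s f^2 / \sum_s(\tilde f - f)^2\right)$ dB
against a clean reference.

## Worked example

Generate the Raman-like benchmark (three Lorentzian peaks over a sqrt
background, 551 points, 20 dB white Gaussian noise), denoise by VMD, and
compare all four methods:

```r
library(vmdenoise)

sig <- gen_signal2(seed = 7)                    # $clean, $noised, $components
res <- denoise_spectrum(sig$noised, "vmd",
                        params    = vmd_params(K = 5),
                        selection = mode_selection("manual", keep = 1:2),
                        reference = sig$clean)
res
#> <denoise_result> method vmd, kept modes {1,2}, SNR 23.34 dB

compare_methods(benchmark_configs(2), noised = sig$noised,
                reference = sig$clean)
#>   method label   snr_db
#> 1     sg    SG 23.42265
#> 2    dwt   DWT 23.70326
#> 3    emd   EMD 23.36620
#> 4    vmd   VMD 23.34190
```

The SNR column scores each denoised estimate against the clean truth; the
noisy input itself sits at 20 dB, so every method buys 3–4 dB here.  The
kept set `{1, 2}` are the two lowest-frequency VMD modes (signal); modes
3–5 are discarded as noise.  For measured spectra (no clean truth) the same
call without `reference` reports a first-difference smoothness diagnostic
instead of SNR.

A thin command-line tool wraps the same functions:

```sh
vmdenoise simulate --signal 2 --seed 7 --out-dir run/
vmdenoise denoise  --method vmd --k 5 --keep 1,2 \
    --input run/noised.csv --reference run/clean.csv \
    --out run/denoised.csv --skip-header
vmdenoise compare  --signal 2 --seeds 1:100 --out run/report.csv
```

Every run writes a JSON manifest (resolved configuration, seed, version)
next to its outputs, and all randomness is a pure function of the seed.

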