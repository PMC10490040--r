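---
title: "Spectral denoising by variational mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral denoising by variational mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmdenoise)
```

## The problem

Raman spectra are weak signals riding on thermal and dark-current noise, and
denoising is a standard preprocessing step before any chemometric analysis.
`vmdenoise` implements a decomposition-based denoiser built on variational
mode decomposition (VMD): the spectrum is split into a small number of
narrowband modes with adaptively estimated center frequencies, the
high-frequency modes (noise) are discarded, and the low-frequency modes
(chemical information) are summed back together.  Empirical mode
decomposition (EMD), Savitzky–Golay (SG) smoothing and discrete-wavelet
thresholding (DWT) are provided as comparators, with a seeded Monte-Carlo
harness that scores all four by signal-to-noise ratio on synthetic
benchmarks where the clean truth is known.

## The VMD model

VMD seeks modes $u_k$, $k = 1..K$, minimizing the summed bandwidth of the
modes subject to (approximate) reconstruction $\sum_k u_k \approx f$.
Bandwidth is measured as the $L^2$ norm of the gradient of each mode's
analytic signal demodulated to its center frequency $\omega_k$.  The
augmented Lagrangian (quadratic penalty $\alpha$, multiplier $\lambda$) is
solved by ADMM, and every sub-problem has a closed form in the Fourier
domain over nonnegative frequencies:

* mode update — a Wiener filter concentrated at $\omega_k$:
  $\hat u_k \leftarrow \dfrac{\hat f - \sum_{i \ne k}\hat u_i + \hat\lambda/2}
  {1 + 2\alpha(\omega - \omega_k)^2}$
* center-frequency update — the power centroid:
  $\omega_k \leftarrow \dfrac{\int_0^{1/2} \omega\,|\hat u_k|^2 d\omega}
  {\int_0^{1/2} |\hat u_k|^2 d\omega}$
* dual ascent: $\hat\lambda \leftarrow \hat\lambda + \tau(\hat f - \sum_k \hat u_k)$.

Iteration stops when the summed relative update norm drops below `tol`.
Modes are transformed back by conjugate-symmetric completion of the half
spectrum (so they are exactly real) and returned sorted by ascending center
frequency, reported both in cycles/sample and—via the grid spacing—in cycles
per axis unit.

### Parameters that matter

* `K` — the number of modes.  There is no universally correct selection
  rule; the bundled benchmark fixtures use `K = 5`, and six modes are a
  reasonable starting point for measured Raman spectra.  `vmd_suggest_k()`
  automates the heuristic "increase K until the top mode chases broadband
  noise past a fraction of Nyquist".
* `alpha` (default 2000) — bandwidth penalty; larger values give narrower
  modes.  Doubling `alpha` never widens a converged mode's spectral
  bandwidth (a tested property).  Very large values slow convergence and can
  leave center frequencies stranded near their initialization.
* `tau` (default 0) — dual ascent step.  `tau = 0` drops the exact
  reconstruction constraint, which is precisely what a denoiser wants: the
  discrepancy $f - \sum_k u_k$ is where the residual noise goes.  With
  `tau > 0` the reconstruction residual decreases monotonically near
  convergence (tested); overdriving `tau` makes the ascent overshoot, which
  the solver reports as divergence (detected by mode-energy blow-up).
* `init` — `"uniform"` spreads starting frequencies over $(0, 0.5)$;
  `"random"` (seeded) reaches the same sorted decomposition on
  well-separated inputs (tested).
* `mirror` (default on) — reflects half the signal length at each end before
  the FFT and crops after, suppressing the wrap-around endpoint artifacts
  that periodic transforms otherwise produce.
* `dc` — pins $\omega_1 = 0$, useful for spectra dominated by a baseline.

## The comparators

**EMD** extracts intrinsic mode functions (IMFs) by sifting: cubic-spline
envelopes through the local maxima and minima, subtract the envelope mean,
repeat.  A candidate is accepted once it is stabilized (Cauchy criterion
`SD < 0.2` between successive sift iterates) *and* certifies the two IMF
conditions — extrema and zero-crossing counts equal or differing by one, and
envelope-mean magnitude at most 10% of the interior amplitude.  Candidates
that exhaust `max_sift_iter = 64` sifts (or lose their extrema mid-sift) are
accepted uncertified and flagged in `params$sift_capped`; requiring
certification rather than the classical SD-only stop is a deliberate choice
so that returned IMFs actually satisfy their defining conditions.
Extraction stops at a near-monotone residual (< 2 interior extrema) or when
the residual energy falls below 5% of the input — without that energy floor
a pure cosine sheds spurious micro-IMFs after its single real one.  Boundary
handling mirrors the two extrema nearest each end before spline fitting.
Sifting is pure subtraction, so `rowSums(modes) + residual` reproduces the
input at machine precision, always.

**SG smoothing** is local least-squares polynomial fitting in an odd window
`2w + 1` (delegated to `signal::sgolayfilt()`, whose projection matrix also
handles the endpoints by evaluating the first/last full-window fit
off-center).  Degree-&le;order polynomials are exact fixed points.  The
default order 3 preserves peak heights better than quadratic fits; even
window requests are bumped to the next odd width with a warning.

**DWT thresholding** uses an in-package multilevel wavelet transform
(half-point symmetric extension, Mallat pyramid) over published orthogonal
filter banks (`haar`, `db2`, `db4`, `sym4`, `sym8`), because no wavelet
package is otherwise available to R here; the filter bank reconstructs
perfectly (~1e-12) at every admissible depth.  Denoising follows the
standard Donoho–Johnstone recipe: noise scale from the finest detail band,
$\sigma = \mathrm{median}(|d_1|)/0.6745$; universal threshold
$\lambda = \sigma\sqrt{2\ln N}$; soft (default) or hard shrinkage of all
detail bands; approximations untouched.  Default wavelet `sym8` at the
maximum useful depth $\lfloor\log_2(n/(L-1))\rfloor$.

## Scoring

The harness scores an estimate $\tilde f$ against the clean reference $f$ as

$$\mathrm{SNR} = 10\log_{10}\frac{\sum_s f^2(x)}{\sum_s(\tilde f(x) - f(x))^2}\ \mathrm{dB},$$

summed over all sample points ("lg" read as base 10 — the only reading
consistent with calibrating noise in dB).  For measured spectra there is no
clean truth; `denoise_spectrum()` then reports only a first-difference
energy as a qualitative smoothness diagnostic, and no SNR.

## The synthetic benchmarks

**Benchmark 1** sums three cosines of well-separated frequencies,
$f_1 = \cos(2\pi\,2x) - 3$, $f_2 = \cos(2\pi\,20x)/4$,
$f_3 = \cos(2\pi\,50x)/6$, plus white Gaussian noise.  The grid is
$x \in [0, 1)$ with $n = 1000$, so the tones complete 2, 20 and 50 cycles
and sit far apart on the frequency axis; the default noise level is
$\sigma = 0.05$.  Both are configurable — the published description of this
experiment fixes neither.

**Benchmark 2** emulates a Raman-like spectrum: three Lorentzian peaks of
differing widths and heights plus a slowly varying background,
$f_4 = 2/((5x-70)^2+3)$, $f_5 = 5/((x-3)^2+3)$, $f_6 = 4/((x+2)^2+4)$,
$f_7 = 0.03\sqrt{x}$, on 551 points spaced 0.1 apart from 0.  The component
evaluator is the generalized Lorentzian $A/((ax-b)^2+c)$, so alternative
parameterizations of these widely-reproduced component definitions are a
one-line configuration change.  White Gaussian noise is injected at a stated
SNR (default 20 dB) with the calibrated closed form
$\sigma = \sqrt{\sum f^2 / (s\,10^{\mathrm{SNR}/10})}$, which makes the
expected realized SNR equal the request; over 200 seeds the realized mean is
within ±0.3 dB (tested).

What the generators deliberately do **not** emulate: Poisson/shot noise,
cosmic-ray spikes, baseline drift beyond the $\sqrt{x}$ term, or
detector-specific correlated noise.  Passing benchmarks therefore
demonstrates correct decomposition and calibration mechanics, not
performance on any particular instrument's spectra.

## Benchmark mode selections

Mode classification mirrors practice: `manual` selection is primary (the
analyst inspects the decomposition), `freq_cut` automates it.  The bundled
fixtures pin:

* benchmark 1 — VMD `K = 5`, keep the three lowest-frequency modes (the
  three cosines); SG window 17; EMD frequency cut at 0.07 cycles/sample.
* benchmark 2 — VMD `K = 5`, keep the two lowest-frequency modes; SG window
  33; EMD frequency cut at 0.04 cycles/sample.

The EMD cuts were chosen by inspecting the decomposition structure: on both
benchmarks the noise concentrates in the leading IMF(s) with spectral
centroids near 0.3 cycles/sample while signal-bearing IMFs sit below
0.03 cycles/sample, so any cut in the wide gap between them removes exactly
the noise IMFs.  An index-based rule ("always remove the first three") is
not portable across sifting implementations, whose IMF counts differ; the
frequency rule expresses the same intent robustly.  The EMD residual trend
always stays with the kept low-frequency side.  The SG window of 17 rounds
up an even window of 16 used in the first benchmark's provenance, per the
odd-window requirement.

## What the comparison shows here

Running `scripts/acceptance.R` (or `compare_methods(benchmark_configs(2),
signal = 2, seeds = 1:100)`) computes, at the default 20 dB calibration,
mean SNRs of roughly 23.4 (SG), 24.4 (DWT), 24.5 (EMD, frequency cut) and
23.3 dB (VMD keep-2) on benchmark 2 — all four methods recover 3–4.5 dB
over the noisy input, within about 1.2 dB of one another.  At this noise
level and with these fairly broad spectral features, the decomposition
methods hold no decisive advantage over well-configured direct filters: the
kept VMD band necessarily truncates some sharp-peak energy (keeping all five
modes of the *clean* signal reconstructs it to < 2% relative error, but two
modes carry only part of the narrow $f_4$ peak), while the universal-threshold
DWT adapts its noise floor per band.  Comparable experiments are often
quoted with substantially lower absolute SNRs (≈15–17 dB), which correspond
to stronger noise or sharper features than these closed-form components
produce; both knobs (`snr_db`, component parameters, `sigma`) are exposed so
such regimes can be explored directly.  VMD's structural advantages —
adaptive band placement without mode mixing, and mirror-extension endpoint
handling — are asserted by the recovery and property tests rather than by
the SNR table.

## Numerical choices and degenerate inputs

* Spectra must be uniformly sampled (relative tolerance 1e-6), length ≥ 8,
  with no missing values — NaN is a hard error, never imputed.  Descending
  axes (common in Raman exports) are silently reversed with a log message.
* All decomposers work on sample index internally; frequencies convert to
  axis units via the grid spacing.
* VMD: `K` may not exceed $\lfloor N/2\rfloor$; a constant signal with
  `dc = TRUE` is a fixed point; mode-energy blow-up (e.g. excessive `tau`)
  raises an error naming `alpha`/`tau`.
* EMD: plateau extrema count once at their midpoint; exact zeros count one
  crossing; a monotone input returns zero IMFs with the input as residual.
* DWT: requesting a level beyond the admissible maximum is an error stating
  that maximum; thresholding never touches approximation coefficients.
* Decomposition files round-trip at 12 significant digits (CSV matrix +
  JSON sidecar).

## Problem sizes used by the test and acceptance runs

Benchmarks run at their native sizes (1000 and 551 points).  Monte-Carlo
summaries use 100 seeds for the four-method comparisons and 200 seeds for
the noise calibration; unit-level property loops use 10–50 seeded fixtures
of 256–1024 points.  These sizes were chosen so the full suite completes in
well under a minute of compute per benchmark while keeping Monte-Carlo
standard errors a fraction of the tolerances tested.

## Known limitations

* `K`, `alpha` and the mode split are user choices; no automatic model
  selection is claimed beyond the `vmd_suggest_k()` heuristic.
* The comparison harness reports SNR only; peak-height retention or RMSE
  metrics are out of scope, as are ensemble EMD variants, CWT denoising and
  2-D (image) decompositions.
* Real measured spectra carry no clean reference, so the pipeline reports
  smoothness diagnostics instead of SNR there, and nothing in the test suite
  certifies denoising quality on measured data.
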