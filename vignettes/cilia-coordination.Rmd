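---
title: "Quantifying cilia coordination: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cilia coordination: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliakit)
```

## The measurement model

A cilium sweeping through a pixel modulates that pixel's transmitted (or
scattered) light at the ciliary beat frequency (CBF). A grayscale
time-lapse stack `I(x, t)` at frame rate `Fs` therefore encodes, pixel by
pixel, an oscillation whose frequency, phase and cross-pixel phase locking
are the observables of cilia coordination. `ciliakit` treats the stack as
a field of univariate time series and derives four layers of description:

1. **CBF map** — per pixel, the band-limited spectral peak:
   `argmax |X(f)|` for `f` in `[f_min, Fs/2]`, with `X` the DFT of the
   mean-subtracted intensity series. The default `f_min = 15` Hz excludes
   slow illumination drift and cell movement; mean subtraction removes the
   DC line so Parseval-based checks stay exact. Ties (discrete spectra can
   tie) go to the lowest frequency for determinism.
2. **Signal mask** — beating cilia occupy only part of the field of view.
   A pixel counts as signal if at least one 3×3 window containing it has a
   frequency standard deviation below 3 Hz (population SD; windows are
   truncated at the image border rather than padded, because zero padding
   would fabricate low-SD borders). Implementation detail with identical
   semantics: threshold the rolling SD, then dilate by the kernel
   footprint. Connected signal components (8-connectivity) below 500 px
   are discarded. The mask is computed on the spatially downsampled grid
   (block averaging, default factor 5), so `min_region` counts
   downsampled pixels.
3. **Frequency patches** — Fourier phases are only comparable within one
   spectral line, and phases of nearby frequency lines of a finite series
   are correlated; so phases are read patch-wise. Peak frequencies are
   quantized into 100 uniform bins over `[0, Fs/2]` (0.54 Hz at
   `Fs = 108`), same-bin signal pixels are grouped by 8-connected
   components, and components under 200 px are dropped. Each patch's
   *dominant frequency* is the spectral line (restricted to the patch's
   bin) maximizing the patch-summed power — the patch-level analogue of
   the per-pixel peak, robust to pixels whose individual peaks straddle
   two lines.
4. **Phase, gradient, wave summary** — per patch, `phi(x) = Arg X(f_dom)`
   wrapped to `(-pi, pi]`; with the `exp(-i 2 pi f t)` transform
   convention a pixel `cos(2 pi f t + phi0)` yields exactly `phi0`. The
   phase gradient (below) gives, per pixel, a local wave vector estimate
   `k = -grad(phi)`: an intensity wave `cos(2 pi f t + phi(x))` propagates
   along the direction of decreasing phase. Per patch we report the
   circular mean of the per-pixel propagation angles, the circular
   standard deviation `sqrt(-2 log Rbar)` of those angles (`Rbar` = mean
   resultant length; rendered as confidence/transparency in figures), and
   the wavelength `lambda = 2 pi / |k|`.

Angles follow the wave-vector parametrization
`(k_x, k_y) = 2 pi / lambda * (-sin theta, cos theta)`: `theta` is
measured from the +y axis (image rows increase downward; `theta = 0` is a
wave traveling "down" the image, along the reference effective-stroke
axis). All coordinates are row-major with origin at the top-left; if the
anatomical stroke axis of a recording is known, rotate reported angles
accordingly.

## Synchronization: magnitude-squared coherence

Two cilia beating at the same frequency need not be synchronized — they
may share a frequency by coincidence. The lag-independent test of phase
locking is the magnitude-squared coherence

`C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))`,

with auto-/cross-spectral densities estimated by Welch's method: Hamming
window of 100 samples, overlap 80, nfft 100 (about 1 Hz resolution at
100 frames/s, and 146 segments in a 30 s recording). Conventions that the
coherence ratio makes irrelevant are nonetheless fixed and asserted in
tests: 'density' normalization `1/(Fs sum(w^2))`, one-sided doubling
except at DC/Nyquist, whole-series mean subtraction (so affine intensity
changes cancel exactly), and `P_xy = <X conj(Y)>` so that a pure delay
`tau` gives `Arg P_xy = +2 pi f tau`. A single Welch segment would make
`C` identically 1, so fewer than two segments is an error; bins where
either series has exactly zero power are reported as `C = 0` with an
`undefined` flag.

Derived products:

* **Reference-pixel maps**: peak coherence over the band (the "peak"
  reduction is the default; coherence evaluated exactly at the reference
  CBF is available via `reduction = "at_ref"` — the peak is robust to
  sub-bin frequency offsets between pixels), and spectral power at the
  reference CBF as a *percentage of the pixel's own band power* (absolute
  power would be intensity-scale dependent, and the 10 %/25 % thresholds
  imply a relative scale).
* **Classification**: synchronized (`C >= 0.5`, power `>= 10 %`), same
  frequency but unsynchronized (`C <= 0.3`, power `>= 25 %`), different
  frequency (`C <= 0.5`, power `<= 25 %`), otherwise "other", applied in
  that priority order (the second and third boxes share only their
  power = 25 % edge).
* **Coherence versus distance**: peak coherence and Euclidean distance
  for unordered signal-pixel pairs, accumulated into 0.5 µm × 0.04
  histograms with per-distance-bin means and the fraction above
  `C > 0.25`. All-pairs on a downsampled mask is O(10^8); the default is
  a seeded uniform subsample of 2×10^5 pairs (drawn with replacement;
  identical histograms in expectation), with exact all-pairs behind
  `n_pairs = Inf`. The default is deliberately smaller than a compiled
  implementation would use — pure-R pair batching is the bottleneck —
  and is a parameter, not a constant.

## Circular phase gradients

Wrapped phase has a ±pi seam that corrupts naive finite differences. The
classical remedy — compute image gradients of both `phi` and
`wrap(phi + pi)` and keep, per pixel, the variant with the smaller
magnitude — fails at steep phase slopes: wrap corruption subtracts 2·pi
from a difference, which can *shrink* the corrupted gradient below the
true one, so min-magnitude selection occasionally picks the aliased
variant. On noise-free 5 µm plane waves at 0.75 µm/px this produced
systematic direction errors of 10–20° at oblique angles. `ciliakit`
therefore builds the same Prewitt operator from *individually wrapped*
centered differences: `D = wrap(phi[i+1] - phi[i-1])` along each axis,
averaged over the three perpendicular taps and divided by the operator
gain (6, expressed as the 2 px baseline times the 3-tap mean) and by the
pixel size, giving rad/µm. This is exact whenever the true two-pixel
phase change plus noise stays below pi — the spatial Nyquist limit of the
phase field itself — and agrees with the two-variant scheme wherever that
scheme is valid. Pixels whose 3×3 neighborhood leaves the patch are
dropped; patches with fewer than 10 valid gradient pixels are flagged
low-confidence.

## Wavelength: mean vector versus modal magnitude

Two reductions of the per-pixel gradient field to a patch wavelength are
in circulation, and they differ materially under noise:

* **Mean gradient vector** (`method = "mean_vector"`, the default):
  `lambda = 2 pi / |mean(g)|`. Zero-mean gradient noise averages out of
  the *vector* mean, so the estimator is unbiased to first order. With
  static per-pixel phase jitter of SD `sigma = 0.2` rad the per-pixel
  gradient noise is `sigma / (sqrt(6) px) ≈ 0.11` rad/µm, yet recovered
  wavelengths across 5–40 µm stay within ~1 % of truth.
* **Modal magnitude** (`method = "mode"`): histogram the per-pixel
  magnitudes `|g|` in 0.01 rad/µm bins and invert the modal bin center.
  The magnitude of a noisy vector is Rician; its mode sits above `|k|` by
  roughly `sigma_g^2 / (2 |k|)`, and the winning bin is itself a noisy
  draw among neighbors. For short wavelengths (large `|k|`) this is
  negligible and the mode is robust to outliers and to mixtures (a patch
  containing 70 % of 10 µm wave and 30 % of 40 µm wave reports 10 µm, not
  a blend); for `lambda >= 20` µm under the jitter above, errors of
  10–30 % are typical. That bias is a property of the estimator, not of
  the pipeline, which is why the unbiased mean-vector reduction is the
  default while the modal one remains available (and is the right tool
  when a patch may contain several coexisting waves).

Either way, an estimate falling into the magnitude bin containing zero
means the patch is synchronous within resolution: the wavelength is
reported capped at `2 pi / mag_bin` (628 µm at the default bin) with a
flag, rather than as an unstable large number.

## The lattice wave model

The idealized cilia carpet is a triangular lattice, basis
`a1 = a (1, 0)`, `a2 = a (1/2, sqrt(3)/2)`, default spacing `a = 18` µm
— one cilium per primitive cell, density `2 / (sqrt(3) a^2) ≈ 0.0036`
µm⁻² — with a 16×16 unit cell under periodic boundary conditions. The
boundary conditions admit exactly `n1 · n2 = 256` plane waves
`k = (p/n1) b1 + (q/n2) b2` (reciprocal basis `b_i · a_j = 2 pi d_ij`),
including the in-phase solution `k = 0`. Each wave is reduced to a
canonical first-Brillouin-zone representative by minimizing `|k|` over
reciprocal translates, ties broken lexicographically — the reduction
affects labeling only, never the wave set, which is closed under the
hexagonal 60° rotation and under time reversal `k -> -k` (both asserted
in tests). `noisy_phase_field()` perturbs a perfect wave with i.i.d.
`N(0, sigma^2)` phase noise plus a global `Uniform[0, 2 pi)` offset, the
standard initial condition for probing how noise degrades metachronal
pumping.

## The synthetic generator: what it emulates, and what not

`generate_recording()` renders
`I(x, t) = B + sum_p 1_p(x) A_p cos(2 pi f_p t + phi_p(x)) + eps(x, t)`
with plane-wave patch phases `phi_p = wrap(-k_p · x + jitter)`, i.i.d.
Gaussian pixel noise `eps`, optional static per-pixel phase jitter, and
optionally *incoherent* patches whose global phase is re-randomized every
Welch-window length — the "same frequency by coincidence" negative
control that must classify as unsynchronized despite high spectral power.
Defaults state realistic acquisition: 100 frames/s, 128×128 px at
0.75 µm/px (the post-downsampling scale of a 0.15 µm/px recording),
frequencies inside (15, Fs/2), amplitude 1 with noise SD 0.2 (SNR 5).

The generator deliberately does *not* emulate optics: no cilium shapes,
motion blur, uneven illumination, focus drift, or correlated (shot/read)
noise; its patches have sharp boundaries and a single frequency each. A
green test on generator scenes therefore establishes the correctness of
the estimators under the stated signal model — it does not establish
robustness to optical artifacts, which must be judged on real recordings
(e.g., by the stability of wave directions across sliding windows).

Two scale notes on the validation suite: end-to-end recovery tests run on
48×48 px × 800-frame scenes rather than full-size stacks — recovery
accuracy there is set by the phase jitter, not by scene size, and the
smaller scenes keep the suite minutes-fast in pure R; coherence negative
controls run on 3000-frame (30 s) scenes because an incoherent patch
re-randomized every 1 s has only `T` independent phase blocks, and with
`T ≈ 10` its chance coherence with a reference can reach 0.3–0.4 — a
property of short controls, not of the classifier.

## Degenerate inputs and numerical conventions

* Recordings must be single-channel, finite, and at least 200 frames
  (two Welch windows) long; integer stacks are promoted to double before
  windowed products.
* Maps are written as 64-bit float TIFFs (`NA` outside the mask) with a
  JSON sidecar for units, pixel size and parameters; the round trip is
  exact. Only baseline uncompressed grayscale TIFF is supported — this
  is an interchange format choice, not a general TIFF implementation.
* Frequency-map ties, patch numbering (raster order of first pixel),
  Brillouin-zone ties, and pair subsampling are all deterministic given
  the seed; `run_pipeline()` reruns byte-identically.
* An empty frequency band, a reference pixel outside the mask, a series
  shorter than one Welch window, overlapping generator patches, and
  sub-Nyquist generator wavelengths (`lambda <= 2 px`) are errors, not
  warnings.

## Known limitations

* Wave direction is reported in image coordinates; comparing absolute
  angles across recordings requires a registered anatomical axis, which
  is out of scope here.
* The wavelength cap (628 µm at the default `mag_bin`) bounds what a
  near-synchronous patch can report; patches genuinely longer-waved than
  the cap are indistinguishable from synchronous ones.
* Coherence significance is not thresholded statistically; the 0.25/0.3/
  0.5 levels are operational conventions carried by the classification
  and histogram summaries.
* Phase is evaluated at one line per patch; patches whose true frequency
  drifts during the recording blur phase and shorten apparent coherence —
  use sliding-window mode (`window_s`, `stride_s`) for nonstationary
  recordings.
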