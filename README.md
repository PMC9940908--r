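# ciliakit

Motile cilia on multiciliated epithelia beat tens of times per second and
coordinate across cell boundaries into metachronal waves. In high-speed
light-transmission (or light-sheet) recordings, each beating cilium makes the
intensity of the pixels it sweeps oscillate at its beat frequency, so a
time-lapse stack carries the full spatial pattern of beat frequency, phase
and synchronization. `ciliakit` turns such stacks — multi-page grayscale
TIFFs with a frame rate and a pixel size — into quantitative maps of cilia
coordination. It is written for the analysis scale typical of a larval
zebrafish nose or brain ventricle recording (~100 frames/s, 20–30 s,
pixel size 0.1–0.3 µm), but nothing in it is organism-specific.

## What it computes

* **Ciliary beat frequency (CBF) maps.** The CBF of a pixel is the frequency
  in the detection band (15 Hz to Nyquist) maximizing |X(f)|, the magnitude
  of the pixel's Fourier transform. Regions of beating cilia are segmented
  from noise by local frequency stability: a pixel is signal if it belongs
  to a 3×3 window whose frequency SD is below 3 Hz, and surviving regions
  must exceed 500 px.
* **Frequency patches.** Signal pixels are quantized into 100 uniform
  frequency bins over [0, Fs/2] (0.54 Hz bins at Fs = 108 Hz) and grouped
  into 8-connected components of at least 200 px. Phases are only comparable
  within one spectral line, so all later phase analysis is per patch.
* **Synchronization by magnitude-squared coherence.** For pixel signals
  x(t), y(t), Welch estimates (Hamming window 100, overlap 80, nfft 100)
  give the coherence

      C_xy(f) = |P_xy(f)|² / (P_xx(f) · P_yy(f)) ∈ [0, 1],

  a lag-independent measure of phase locking. The package produces
  reference-pixel coherence maps, the coherence/spectral-power pixel
  classification (synchronized: C ≥ 0.5 and power ≥ 10 %; same frequency
  but unsynchronized: C ≤ 0.3 and power ≥ 25 %; different frequency:
  C ≤ 0.5 and power ≤ 25 %), and coherence-versus-distance histograms
  (0.5 µm × 0.04 bins; fraction coherent at C > 0.25).
* **Metachronal wave direction and wavelength.** Per patch, the Fourier
  phase φ(x) at the patch's dominant frequency is extracted for every
  pixel, and circular-aware Prewitt gradients ∇φ are summarized into the
  wave direction (circular mean of the propagation angle, with circular
  SD √(−2 ln R̄) as confidence) and the wavelength λ = 2π/|k|. Angles use
  the wave-vector convention (k_x, k_y) = 2π/λ · (−sin θ, cos θ) with
  θ = 0 along +y.
* **Triangular-lattice wave model.** The admissible perfect traveling
  waves of a periodic 16×16 cilia carpet with 18 µm spacing
  (density 2/(√3 a²) ≈ 0.0036 µm⁻²), noisy plane-wave phase fields, and
  wave-vector/angle conversions.
* **Synthetic recordings with ground truth** (`generate_recording()`), so
  every stage above is testable without raw microscopy data.

## Worked example

```r
library(ciliakit)

# a synthetic recording: one patch beating at 25 Hz, carrying a plane
# wave traveling at 45 deg with an 18 um wavelength, plus phase jitter
scene <- scene_spec(list(
  patch_spec(c(1, 1, 60, 60), frequency = 25, theta = 45, wavelength = 18,
             phase_jitter_sd = 0.1)),
  frame_count = 600, frame_rate = 100, shape = c(60L, 60L),
  pixel_size = 0.75, pixel_noise_sd = 0.2, seed = 3)
g <- generate_recording(scene)

res <- run_pipeline(g$recording, config = pipeline_config(downsample = 1,
                                                          min_region = 400L))
res$waves[, c("dominant_freq", "mean_direction_deg", "circular_sd",
              "wavelength_um")]
#>   dominant_freq mean_direction_deg circular_sd wavelength_um
#> 1            25           44.95160   0.1582546      18.00828
```

The patch is recovered at its true frequency (25 Hz); the wave direction
(44.95°, true 45°) comes with a circular SD of 0.16 — small, so the
per-pixel gradient directions agree — and the wavelength is 18.01 µm
against a ground truth of 18 µm. On real data, start from
`load_recording("stack.tif", frame_rate, pixel_size)` and keep the default
`downsample = 5`.

The same analyses are scriptable from a shell via
`inst/cli/ciliakit.R` (subcommands `cbf`, `patch`, `coherence`, `cohdist`,
`waves`, `run`, `lattice`, `synth`, `morpho`):

```sh
Rscript inst/cli/ciliakit.R morpho --n 47.7 --area 17.4
#> {"density_per_um2":2.741379,"spacing_um":0.681507}
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

generates a seeded two-patch traveling-wave scene, runs the complete
pipeline on it (CBF map, mask, patches, phases, wave table, coherence
stage), logs the recovered per-patch frequency/direction/wavelength, and
writes the JSON result file.
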