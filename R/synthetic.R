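# Synthetic traveling-wave recordings with known ground truth. Every
# analysis stage in the package can be validated against these scenes
# without any microscopy data: each patch oscillates at a chosen frequency
# with a plane-wave phase field phi(x) = wrap(-k . x + jitter), so the wave
# travels along +k, i.e. along the direction theta of
# angle_to_wavevector(theta, lambda).

#' Patch specification for synthetic scenes
#'
#' @param region either a logical matrix (scene geometry) or a rectangle
#'   `c(row0, col0, row1, col1)` (inclusive, 1-based).
#' @param frequency beat frequency in Hz.
#' @param amplitude oscillation amplitude in intensity units.
#' @param theta wave direction in degrees (wave-vector convention:
#'   0 = along +y / down image rows).
#' @param wavelength wavelength in um (`Inf` = synchronous patch; must
#'   exceed `2 * pixel_size` otherwise).
#' @param phase_jitter_sd static per-pixel phase noise SD in rad.
#' @param incoherent if `TRUE`, the patch phase offset is re-randomized
#'   every `incoherent_block` frames, producing a signal that shares its
#'   frequency with a coherent patch while having (near-)zero long-run
#'   coherence — the "same frequency by coincidence" negative control.
#' @param incoherent_block frames per random-phase block (default: one
#'   Welch window length).
#' @return An object of class `cilia_patch_spec`.
#' @export
patch_spec <- function(region, frequency, amplitude = 1, theta = 0,
                       wavelength = Inf, phase_jitter_sd = 0,
                       incoherent = FALSE, incoherent_block = 100L) {
  stopifnot(frequency > 0, amplitude > 0, wavelength > 0,
            phase_jitter_sd >= 0)
  structure(list(region = region, frequency = frequency,
                 amplitude = amplitude, theta = theta,
                 wavelength = wavelength,
                 phase_jitter_sd = phase_jitter_sd,
                 incoherent = incoherent,
                 incoherent_block = as.integer(incoherent_block)),
            class = "cilia_patch_spec")
}

#' Scene specification for synthetic recordings
#'
#' Defaults state the world the analysis expects: 100 frames/s, a
#' 128 x 128 px field at 0.75 um/px (the post-downsampling scale of a
#' 0.15 um/px recording reduced by the standard factor 5), patch
#' frequencies inside the 15 Hz-Nyquist detection band, and i.i.d.
#' Gaussian pixel noise.
#'
#' @param patches list of [patch_spec()]s; regions must not overlap.
#' @param frame_count number of frames.
#' @param frame_rate Hz.
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param background mean background intensity.
#' @param pixel_noise_sd SD of the i.i.d. Gaussian noise added to every
#'   pixel and frame (an amplitude-1 patch at the default 0.2 has SNR 5).
#' @param seed RNG seed; identical specs and seeds give identical stacks.
#' @return An object of class `cilia_scene_spec`.
#' @export
scene_spec <- function(patches, frame_count = 2000L, frame_rate = 100,
                       shape = c(128L, 128L), pixel_size = 0.75,
                       background = 100, pixel_noise_sd = 0.2, seed = 1L) {
  stopifnot(frame_count >= 2, frame_rate > 0, pixel_size > 0,
            pixel_noise_sd >= 0, length(shape) == 2)
  if (inherits(patches, "cilia_patch_spec")) patches <- list(patches)
  for (p in patches) {
    stopifnot(inherits(p, "cilia_patch_spec"))
    if (p$frequency <= 15 || p$frequency >= frame_rate / 2)
      stopf("patch frequency %g Hz outside the detectable band (15, %g) Hz",
            p$frequency, frame_rate / 2)
    if (is.finite(p$wavelength) && p$wavelength <= 2 * pixel_size)
      stopf("wavelength %g um violates the spatial Nyquist limit (> %g um)",
            p$wavelength, 2 * pixel_size)
  }
  structure(list(patches = patches, frame_count = as.integer(frame_count),
                 frame_rate = frame_rate, shape = as.integer(shape),
                 pixel_size = pixel_size, background = background,
                 pixel_noise_sd = pixel_noise_sd, seed = seed),
            class = "cilia_scene_spec")
}

region_mask <- function(region, shape) {
  if (is.matrix(region)) {
    stopifnot(identical(dim(region), as.integer(shape)))
    return(region)
  }
  stopifnot(length(region) == 4)
  m <- matrix(FALSE, shape[1], shape[2])
  m[region[1]:region[3], region[2]:region[4]] <- TRUE
  m
}

#' Generate a synthetic recording with ground truth
#'
#' Renders `I(x, t) = B + sum_p 1_p(x) A_p cos(2 pi f_p t + phi_p(x)) +
#' eps(x, t)` with `phi_p(x) = wrap(-k_p . x + jitter)` and
#' `k_p = angle_to_wavevector(theta_p, lambda_p)`; `eps` is i.i.d.
#' Gaussian pixel noise. Pixel positions are `(x, y) = (col, row) *
#' pixel_size` in the image frame (+y down rows), matching the analysis
#' convention, so the recovered wave direction of patch `p` should equal
#' `theta_p` and the wavelength `lambda_p`.
#'
#' @param spec a [scene_spec()].
#' @return A list: `recording` (a [recording()]), `truth` (data frame with
#'   per-patch `patch`, `frequency`, `theta`, `wavelength`, `amplitude`,
#'   `n_pixels`), `phase` (matrix of ground-truth phases, `NA` off-patch),
#'   `labels` (integer matrix of patch ids).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "cilia_scene_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  nt <- spec$frame_count
  labels <- matrix(0L, nr, nc)
  masks <- lapply(spec$patches, function(p) region_mask(p$region, spec$shape))
  for (i in seq_along(masks)) {
    if (any(labels[masks[[i]]] != 0L)) stopf("patch regions overlap")
    labels[masks[[i]]] <- i
  }
  phase <- matrix(NA_real_, nr, nc)
  t_axis <- (seq_len(nt) - 1) / spec$frame_rate
  with_seed(spec$seed, {
    flat <- matrix(stats::rnorm(nt * nr * nc, spec$background,
                                spec$pixel_noise_sd), nt, nr * nc)
    for (i in seq_along(spec$patches)) {
      p <- spec$patches[[i]]
      pix <- which(masks[[i]])
      rows <- ((pix - 1L) %% nr) + 1L
      cols <- ((pix - 1L) %/% nr) + 1L
      if (is.finite(p$wavelength)) {
        k <- angle_to_wavevector(p$theta, p$wavelength)
        phi <- -(k$kx * cols * spec$pixel_size + k$ky * rows * spec$pixel_size)
      } else {
        phi <- rep(0, length(pix))
      }
      if (p$phase_jitter_sd > 0)
        phi <- phi + stats::rnorm(length(pix), 0, p$phase_jitter_sd)
      phi <- wrap_pi(phi)
      phase[pix] <- phi
      arg <- outer(2 * pi * p$frequency * t_axis, phi, "+")   # nt x npix
      if (p$incoherent) {
        blocks <- ceiling(nt / p$incoherent_block)
        offs <- stats::runif(blocks, 0, 2 * pi)
        arg <- arg + offs[rep(seq_len(blocks),
                              each = p$incoherent_block)[seq_len(nt)]]
      }
      flat[, pix] <- flat[, pix] + p$amplitude * cos(arg)
    }
    stack <- array(flat, dim = c(nt, nr, nc))
  })
  truth <- data.frame(
    patch = seq_along(spec$patches),
    frequency = vapply(spec$patches, `[[`, numeric(1), "frequency"),
    theta = vapply(spec$patches, `[[`, numeric(1), "theta"),
    wavelength = vapply(spec$patches, `[[`, numeric(1), "wavelength"),
    amplitude = vapply(spec$patches, `[[`, numeric(1), "amplitude"),
    incoherent = vapply(spec$patches, `[[`, logical(1), "incoherent"),
    n_pixels = vapply(masks, sum, numeric(1)))
  list(recording = recording(stack, spec$frame_rate, spec$pixel_size,
                             origin_note = "synthetic scene"),
       truth = truth, phase = phase, labels = labels)
}

#' Generate a pair of noisy tones
#'
#' Fixture for coherence tests: `x = cos(2 pi f t) + noise` and
#' `y = cos(2 pi f t + lag) + independent noise`, both at amplitude
#' signal-to-noise ratio `snr` (`Inf` = noise-free). With
#' `per_segment_lag = TRUE` the lag of `y` is re-randomized every `block`
#' samples, destroying coherence while preserving frequency content.
#'
#' @param f tone frequency, Hz (`< fs / 2`).
#' @param lag phase lag of `y` in rad.
#' @param snr amplitude / noise-SD ratio.
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @param per_segment_lag re-randomize the lag of `y` per block.
#' @param block samples per lag block.
#' @return A list with vectors `x` and `y`.
#' @export
generate_pair <- function(f, lag = 0, snr = Inf, n = 3000L, fs = 100,
                          seed = 1L, per_segment_lag = FALSE, block = 100L) {
  stopifnot(f < fs / 2)
  t_axis <- (seq_len(n) - 1) / fs
  sd <- if (is.infinite(snr)) 0 else 1 / snr
  with_seed(seed, {
    x <- cos(2 * pi * f * t_axis)
    if (per_segment_lag) {
      blocks <- ceiling(n / block)
      lags <- stats::runif(blocks, 0, 2 * pi)
      y <- cos(2 * pi * f * t_axis +
                 lags[rep(seq_len(blocks), each = block)[seq_len(n)]])
    } else {
      y <- cos(2 * pi * f * t_axis + lag)
    }
    if (sd > 0) {
      x <- x + stats::rnorm(n, 0, sd)
      y <- y + stats::rnorm(n, 0, sd)
    }
  })
  list(x = x, y = y)
}
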