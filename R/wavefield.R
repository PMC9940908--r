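# Metachronal wave extraction: per-pixel Fourier phase at each patch's
# dominant frequency, circular-aware Prewitt gradients, and per-patch
# direction / wavelength summaries.

#' Phase map at each patch's dominant frequency
#'
#' For all pixels of a patch, the argument of the complex Fourier
#' coefficient at the patch's dominant frequency, wrapped to `(-pi, pi]`.
#' Evaluating all phases of a patch at one frequency line makes them
#' directly comparable; phases read at different lines are not.
#'
#' With the `exp(-i 2 pi f t)` transform convention used here, a pixel with
#' intensity `cos(2 pi f t + phi0)` has phase exactly `phi0`.
#'
#' @param spectra a [pixel_spectra()] result.
#' @param patch_map a [segment_frequency_patches()] result carrying
#'   `dominant_freq` (see [patch_dominant_frequency()]; computed here if
#'   absent).
#' @return A [map_image()] with units `"rad"`, defined exactly on labeled
#'   pixels; `params$eval_freq` lists the per-patch evaluation frequency.
#' @export
phase_map <- function(spectra, patch_map) {
  stopifnot(inherits(spectra, "cilia_spectra"),
            inherits(patch_map, "cilia_patches"))
  if (is.null(patch_map$patches$dominant_freq))
    patch_map <- patch_dominant_frequency(patch_map, spectra)
  d <- dim(spectra$coefficients)
  phases <- matrix(NA_real_, d[2], d[3])
  for (p in seq_len(patch_map$n_patches)) {
    fi <- which.min(abs(spectra$freqs - patch_map$patches$dominant_freq[p]))
    plane <- spectra$coefficients[fi, , ]
    pix <- patch_map$labels == p
    phases[pix] <- Arg(plane[pix])
  }
  map_image(phases, units = "rad", mask = patch_map$labels > 0L,
            pixel_size = spectra$pixel_size,
            params = list(eval_freq = patch_map$patches$dominant_freq))
}

# Centered differences along one axis, each difference wrapped to
# (-pi, pi]; NA where the stencil leaves `valid`.
wrapped_central_diff <- function(phi, valid, along = c("col", "row")) {
  along <- match.arg(along)
  nr <- nrow(phi); nc <- ncol(phi)
  D <- matrix(NA_real_, nr, nc)
  if (along == "col" && nc >= 3) {
    ok <- valid[, 1:(nc - 2)] & valid[, 2:(nc - 1)] & valid[, 3:nc]
    d <- wrap_pi(phi[, 3:nc] - phi[, 1:(nc - 2)])
    d[!ok] <- NA_real_
    D[, 2:(nc - 1)] <- d
  } else if (along == "row" && nr >= 3) {
    ok <- valid[1:(nr - 2), ] & valid[2:(nr - 1), ] & valid[3:nr, ]
    d <- wrap_pi(phi[3:nr, ] - phi[1:(nr - 2), ])
    d[!ok] <- NA_real_
    D[2:(nr - 1), ] <- d
  }
  D
}

# Average a matrix over a 3-tap stencil perpendicular to the difference
# axis; NA propagates, so only fully in-patch 3x3 windows survive.
smooth3 <- function(D, along = c("col", "row")) {
  along <- match.arg(along)
  nr <- nrow(D); nc <- ncol(D)
  S <- matrix(NA_real_, nr, nc)
  if (along == "row" && nr >= 3) {
    S[2:(nr - 1), ] <- (D[1:(nr - 2), ] + D[2:(nr - 1), ] + D[3:nr, ]) / 3
  } else if (along == "col" && nc >= 3) {
    S[, 2:(nc - 1)] <- (D[, 1:(nc - 2)] + D[, 2:(nc - 1)] + D[, 3:nc]) / 3
  }
  S
}

#' Circular-aware phase gradient field
#'
#' Prewitt 3x3 gradients of the wrapped phase field, made circular by
#' wrapping every centered pixel difference to `(-pi, pi]` before the
#' Prewitt row/column averaging. This is exact whenever the true phase
#' change over two pixels (plus noise) stays below pi — the spatial
#' Nyquist limit of the phase field — and is equivalent to, but strictly
#' more robust than, computing plain Prewitt gradients on both `phi` and
#' `wrap(phi + pi)` and keeping the seam-free variant: at steep phase
#' slopes the wrap seam can *shrink* the corrupted gradient, so a
#' smaller-magnitude selection between the two variants picks the aliased
#' estimate (see the methods vignette). Gradients are normalized by the
#' Prewitt gain (6) and by the pixel size, giving rad/um. Pixels whose
#' 3x3 neighborhood leaves their patch are dropped.
#'
#' @param phase a [phase_map()].
#' @param patch_map the [segment_frequency_patches()] result that defined
#'   the phase map.
#' @param pixel_size um per pixel (default: taken from the phase map).
#' @return An object of class `cilia_gradient`: matrices `gx`, `gy`
#'   (rad/um, `NA` where undefined), `magnitude`, `direction` (rad, the
#'   image-frame angle `atan2(gy, gx)` of the phase gradient), and
#'   `labels` (patch labels restricted to valid gradient pixels).
#' @export
circular_gradient <- function(phase, patch_map, pixel_size = phase$pixel_size) {
  stopifnot(inherits(phase, "cilia_map"), inherits(patch_map, "cilia_patches"))
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be positive (got %s)", format(pixel_size))
  labels <- patch_map$labels
  nr <- nrow(labels); nc <- ncol(labels)
  gx <- matrix(NA_real_, nr, nc); gy <- gx
  for (p in seq_len(patch_map$n_patches)) {
    inpatch <- labels == p
    phi <- phase$values
    # Prewitt = centered difference (over 2 px) averaged over the 3
    # perpendicular taps; wrapping each difference handles the +-pi seam
    Dx <- wrapped_central_diff(phi, inpatch, "col")
    Dy <- wrapped_central_diff(phi, inpatch, "row")
    px_g <- smooth3(Dx, "row") / (2 * pixel_size)
    py_g <- smooth3(Dy, "col") / (2 * pixel_size)
    keep <- inpatch & !is.na(px_g) & !is.na(py_g)
    gx[keep] <- px_g[keep]
    gy[keep] <- py_g[keep]
  }
  magnitude <- sqrt(gx^2 + gy^2)
  direction <- atan2(gy, gx)
  glabels <- labels
  glabels[is.na(gx)] <- 0L
  structure(list(gx = gx, gy = gy, magnitude = magnitude,
                 direction = direction, labels = glabels,
                 pixel_size = pixel_size,
                 n_patches = patch_map$n_patches),
            class = "cilia_gradient")
}

# Propagation angle (deg, [0, 360)) of a wave crest from its phase
# gradient: intensity cos(2 pi f t + phi(x)) travels along -grad(phi), and
# angles follow the wave-vector convention theta = atan2(-kx, ky)
# (theta = 0 along +y, i.e. down image rows).
propagation_angle_deg <- function(gx, gy) {
  wrap_deg(atan2(gx, -gy) * 180 / pi)
}

#' Per-patch wave direction
#'
#' The wave direction of a patch is the circular mean of the per-pixel
#' propagation angles derived from the phase gradient (a wave
#' `cos(2 pi f t + phi(x))` travels along `-grad(phi)`); its dispersion is
#' the circular standard deviation `sqrt(-2 log Rbar)` of those angles,
#' where `Rbar` is the mean resultant length. Angles follow the wave-vector
#' convention: `theta = 0` along +y (down image rows), measured toward -x.
#' Patches with fewer than `min_pixels` valid gradient pixels are flagged
#' low-confidence.
#'
#' @param grad a [circular_gradient()] result.
#' @param min_pixels minimum valid gradient pixels for a confident estimate.
#' @return A data frame: `label`, `n_gradient_pixels`, `mean_direction_deg`
#'   (`[0, 360)`), `circular_sd`, `low_confidence`.
#' @export
wave_direction <- function(grad, min_pixels = 10L) {
  stopifnot(inherits(grad, "cilia_gradient"))
  out <- data.frame(label = seq_len(grad$n_patches),
                    n_gradient_pixels = 0L,
                    mean_direction_deg = NA_real_,
                    circular_sd = NA_real_,
                    low_confidence = TRUE)
  for (p in seq_len(grad$n_patches)) {
    pix <- grad$labels == p
    theta <- propagation_angle_deg(grad$gx[pix], grad$gy[pix]) * pi / 180
    st <- circ_stats(theta)
    out$n_gradient_pixels[p] <- length(theta)
    out$mean_direction_deg[p] <- wrap_deg(st$mean * 180 / pi)
    out$circular_sd[p] <- circ_sd(st$R)
    out$low_confidence[p] <- length(theta) < min_pixels
  }
  out
}

#' Per-patch wavelength
#'
#' `method = "mean_vector"` (default): `2 pi` over the length of the mean
#' gradient *vector* of the patch. Zero-mean per-pixel gradient noise
#' averages out of the mean vector, so this estimator recovers plane-wave
#' wavelengths of 5-40 um to within a few percent under realistic phase
#' jitter.
#'
#' `method = "mode"`: histogram of the per-pixel gradient magnitudes with
#' bin width `mag_bin`; the wavelength is `2 pi` over the modal bin
#' center. The magnitude of a noisy gradient is Rician: its mode
#' overestimates `|k|` by about `sigma_g^2 / (2 |k|)`, and the modal bin
#' itself is a noisy draw among neighboring bins, so this estimator
#' degrades for long wavelengths (small `|k|`); it is retained because it
#' is robust to magnitude outliers and to multi-modal patches (a mixture
#' of wavelengths yields the majority mode, not a blend). See the methods
#' vignette for the choice of default.
#'
#' Either way a patch whose estimate falls in the magnitude bin containing
#' zero is (near-)synchronous: its wavelength is reported as the cap
#' `2 pi / mag_bin` with `capped = TRUE`.
#'
#' @param grad a [circular_gradient()] result.
#' @param mag_bin rad/um, histogram bin width for the modal magnitude
#'   (also the resolution floor below which a patch counts as synchronous).
#' @param method `"mean_vector"` or `"mode"`.
#' @return A data frame: `label`, `wavelength_um`, `capped`.
#' @export
wavelength <- function(grad, mag_bin = 0.01, method = c("mean_vector", "mode")) {
  stopifnot(inherits(grad, "cilia_gradient"))
  method <- match.arg(method)
  out <- data.frame(label = seq_len(grad$n_patches),
                    wavelength_um = NA_real_, capped = FALSE)
  cap <- 2 * pi / mag_bin
  for (p in seq_len(grad$n_patches)) {
    pix <- grad$labels == p
    if (!any(pix)) next
    if (method == "mode") {
      m <- grad$magnitude[pix]
      bins <- floor(m / mag_bin)
      tab <- table(bins)
      modal <- as.numeric(names(tab)[which.max(tab)])
      if (modal == 0) {
        out$wavelength_um[p] <- cap
        out$capped[p] <- TRUE
      } else {
        out$wavelength_um[p] <- 2 * pi / ((modal + 0.5) * mag_bin)
      }
    } else {
      k <- sqrt(mean(grad$gx[pix])^2 + mean(grad$gy[pix])^2)
      if (k < mag_bin / 2) {
        out$wavelength_um[p] <- cap
        out$capped[p] <- TRUE
      } else {
        out$wavelength_um[p] <- 2 * pi / k
      }
    }
  }
  out
}

#' Per-patch wave summary
#'
#' Convenience wrapper combining [wave_direction()] and [wavelength()]
#' with the patch table (dominant frequency, size).
#'
#' @inheritParams circular_gradient
#' @inheritParams wavelength
#' @param min_pixels see [wave_direction()].
#' @return A data frame, one row per patch: `label`, `n_pixels`,
#'   `dominant_freq`, `n_gradient_pixels`, `mean_direction_deg`,
#'   `circular_sd`, `wavelength_um`, `capped`, `low_confidence`.
#' @export
wave_field <- function(phase, patch_map, pixel_size = phase$pixel_size,
                       mag_bin = 0.01, min_pixels = 10L,
                       method = c("mean_vector", "mode")) {
  grad <- circular_gradient(phase, patch_map, pixel_size)
  dirs <- wave_direction(grad, min_pixels = min_pixels)
  lams <- wavelength(grad, mag_bin = mag_bin, method = method)
  base <- patch_map$patches[, intersect(c("label", "n_pixels", "dominant_freq"),
                                        names(patch_map$patches))]
  out <- merge(merge(base, dirs, by = "label"), lams, by = "label")
  out[order(out$label), ]
}
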