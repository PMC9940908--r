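#' Spatially downsample a recording by block averaging
#'
#' Each frame is reduced by averaging non-overlapping `factor` x `factor`
#' pixel blocks (trailing partial blocks are dropped); the time axis is
#' untouched and the pixel size is multiplied by `factor`. Downsampling by 5
#' is the standard speed/SNR trade-off before per-pixel spectral analysis.
#'
#' @param rec a [recording()].
#' @param factor positive integer block size; `1` returns the input.
#' @return A [recording()] with reduced spatial dimensions.
#' @export
downsample_stack <- function(rec, factor = 5L) {
  stopifnot(inherits(rec, "cilia_recording"))
  if (!is_count(factor)) stopf("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  d <- dim(rec$stack)
  nr <- (d[2] %/% factor) * factor
  nc <- (d[3] %/% factor) * factor
  if (nr < factor || nc < factor)
    stopf("frame (%d x %d) smaller than one %d x %d block", d[2], d[3],
          factor, factor)
  x <- rec$stack[, seq_len(nr), seq_len(nc), drop = FALSE]
  # collapse each factor x factor block: split both spatial axes into
  # (block index, within-block index) and average the within-block axes
  dim(x) <- c(d[1], factor, nr %/% factor, factor, nc %/% factor)
  x <- aperm(x, c(1, 3, 5, 2, 4))
  dim(x) <- c(d[1] * (nr %/% factor) * (nc %/% factor), factor * factor)
  x <- rowMeans(x)
  dim(x) <- c(d[1], nr %/% factor, nc %/% factor)
  recording(x, rec$frame_rate, rec$pixel_size * factor, rec$origin_note)
}

#' Per-pixel Fourier spectra
#'
#' Computes the one-sided discrete Fourier transform of every pixel's
#' mean-subtracted intensity time series. The DC coefficient is zero by
#' construction, so Parseval's identity relates the remaining coefficients
#' to the temporal variance of each pixel.
#'
#' @param rec a [recording()] with at least `min_frames` frames.
#' @param min_frames guard against series too short for stable spectra.
#' @return An object of class `cilia_spectra`: `coefficients` (complex
#'   array, n_freq x rows x cols), `freqs` (Hz, length
#'   `floor(n_frames/2) + 1`), `frame_rate`, `pixel_size`, `n_frames`.
#' @export
pixel_spectra <- function(rec, min_frames = 200L) {
  stopifnot(inherits(rec, "cilia_recording"))
  d <- dim(rec$stack)
  if (d[1] < min_frames)
    stopf("need at least %d frames for spectral analysis, got %d",
          min_frames, d[1])
  n <- d[1]
  x <- rec$stack
  dim(x) <- c(n, d[2] * d[3])          # columns are pixel time series
  x <- sweep(x, 2L, colMeans(x), "-")
  coef <- stats::mvfft(x)
  n_freq <- n %/% 2L + 1L
  coef <- coef[seq_len(n_freq), , drop = FALSE]
  dim(coef) <- c(n_freq, d[2], d[3])
  structure(
    list(coefficients = coef,
         freqs = (seq_len(n_freq) - 1) * rec$frame_rate / n,
         frame_rate = rec$frame_rate, pixel_size = rec$pixel_size,
         n_frames = n),
    class = "cilia_spectra")
}

#' @export
print.cilia_spectra <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf(
    "<cilia_spectra> %d x %d px, %d frequency lines (0-%.4g Hz, df=%.4g Hz)\n",
    d[2], d[3], d[1], max(x$freqs), x$freqs[2]))
  invisible(x)
}

#' Peak-frequency (CBF) map
#'
#' The ciliary beat frequency of a pixel is the frequency, within a search
#' band, at which the magnitude of its Fourier transform is maximal. The
#' default band starts at 15 Hz (excluding slow intensity drift) and ends at
#' the Nyquist frequency. Ties are broken toward the lowest frequency.
#'
#' @param spectra a [pixel_spectra()] result.
#' @param f_min,f_max band edges in Hz (inclusive).
#' @return A [map_image()] with units `"Hz"`, mask all-`TRUE` (signal/noise
#'   segmentation is a separate step, [signal_mask()]), and the band stored
#'   in `params`.
#' @export
peak_frequency_map <- function(spectra, f_min = 15,
                               f_max = spectra$frame_rate / 2) {
  stopifnot(inherits(spectra, "cilia_spectra"))
  if (!(f_min < f_max) || f_max > spectra$frame_rate / 2 + 1e-9)
    stopf("need f_min < f_max <= Nyquist (%.4g Hz)", spectra$frame_rate / 2)
  sel <- which(spectra$freqs >= f_min & spectra$freqs <= f_max)
  if (length(sel) == 0) stopf("no frequency line in [%g, %g] Hz", f_min, f_max)
  d <- dim(spectra$coefficients)
  a <- abs(spectra$coefficients[sel, , , drop = FALSE])
  dim(a) <- c(length(sel), d[2] * d[3])
  idx <- max.col(t(a), ties.method = "first")
  vals <- matrix(spectra$freqs[sel[idx]], d[2], d[3])
  map_image(vals, units = "Hz", pixel_size = spectra$pixel_size,
            params = list(f_min = f_min, f_max = f_max))
}

# Rolling window sums with border truncation: for each pixel, the sum of
# `x` over the (2h+1)^2 window centred there, windows clipped at the image
# border. Returns list(sum, n).
rolling_window_sum <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  s <- matrix(0, nr, nc); n <- matrix(0L, nr, nc)
  for (dr in -h:h) {
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    r_src <- r_dst + dr
    for (dc in -h:h) {
      c_dst <- max(1, 1 - dc):min(nc, nc - dc)
      c_src <- c_dst + dc
      s[r_dst, c_dst] <- s[r_dst, c_dst] + x[r_src, c_src]
      n[r_dst, c_dst] <- n[r_dst, c_dst] + 1L
    }
  }
  list(sum = s, n = n)
}

# Binary dilation by a (2h+1)^2 square footprint, border-clipped.
dilate_square <- function(mask, h) {
  rolling_window_sum(mask * 1, h)$sum > 0
}

# 8- or 4-connected component labeling of a logical matrix via igraph.
# Returns an integer matrix, 0 = background, components numbered in raster
# (row-major) order of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (o in offs) {
    r <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c <- max(1, 1 - o[2]):min(nc, nc - o[2])
    a <- id[r, c, drop = FALSE]
    b <- id[r + o[1], c + o[2], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- rbind(a[keep], b[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  memb <- igraph::components(g)$membership
  # renumber components in raster order of their first pixel
  rc_row <- ((idx - 1L) %% nr) + 1L
  rc_col <- ((idx - 1L) %/% nr) + 1L
  raster_pos <- (rc_row - 1L) * nc + rc_col
  first_pos <- tapply(raster_pos, memb, min)
  new_id <- integer(length(first_pos))
  new_id[order(first_pos)] <- seq_along(first_pos)
  labels[idx] <- new_id[memb]
  labels
}

#' Segment a frequency map into signal and noise pixels
#'
#' Beating cilia do not cover the whole field of view. A pixel is classed as
#' signal if it belongs to at least one `kernel` x `kernel` window whose
#' standard deviation of peak frequency is below `sd_threshold`
#' (equivalently: the rolling-SD map is thresholded and then dilated by the
#' kernel footprint). Connected signal regions (8-connectivity) smaller than
#' `min_region` pixels are then discarded. Windows are truncated at the
#' image border rather than padded; the SD is the population (n-divisor)
#' standard deviation.
#'
#' @param freq_map a [peak_frequency_map()] result.
#' @param kernel odd window size >= 3.
#' @param sd_threshold Hz; windows with SD strictly below this pass.
#' @param min_region smallest surviving connected signal region, in pixels
#'   of the (possibly downsampled) map.
#' @return A boolean [map_image()] (units `"dimensionless"`); `values` is
#'   the 0/1 signal indicator and `mask` the signal pixels.
#' @export
signal_mask <- function(freq_map, kernel = 3L, sd_threshold = 3,
                        min_region = 500L) {
  stopifnot(inherits(freq_map, "cilia_map"))
  if (!is_count(kernel) || kernel < 3 || kernel %% 2 == 0)
    stopf("kernel must be an odd integer >= 3")
  f <- freq_map$values
  if (any(!is.finite(f))) stopf("frequency map must be finite everywhere")
  h <- (as.integer(kernel) - 1L) %/% 2L
  s1 <- rolling_window_sum(f, h)
  s2 <- rolling_window_sum(f^2, h)
  v <- s2$sum / s1$n - (s1$sum / s1$n)^2
  sd_map <- sqrt(pmax(v, 0))
  passes <- sd_map < sd_threshold
  signal <- dilate_square(passes, h)
  labels <- label_components(signal, 8L)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0L])
    signal[labels > 0L & sizes[pmax(labels, 1L)] < min_region] <- FALSE
  }
  map_image(signal * 1, units = "dimensionless", mask = signal,
            pixel_size = freq_map$pixel_size,
            params = list(kernel = kernel, sd_threshold = sd_threshold,
                          min_region = min_region))
}
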