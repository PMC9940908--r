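#' Welch estimation parameters
#'
#' Spectral estimates for coherence use Welch's method: the series is cut
#' into overlapping segments, each tapered with a Hamming window and
#' Fourier transformed, and the (cross-)periodograms are averaged. The
#' defaults — 100-sample Hamming window, 80-sample overlap, 100-point FFT —
#' give a ~1 Hz frequency resolution at ~100 frames/s and enough segments
#' in a 30 s recording for a stable coherence estimate.
#'
#' @param window_length samples per segment (Hamming taper).
#' @param overlap samples shared by consecutive segments
#'   (`0 <= overlap < window_length`).
#' @param n_fft FFT length (`>= window_length`; segments are zero-padded).
#' @param frame_rate sampling rate in Hz.
#' @return An object of class `welch_spec`.
#' @export
welch_spec <- function(window_length = 100L, overlap = 80L, n_fft = 100L,
                       frame_rate = 100) {
  stopifnot(is_count(window_length), n_fft >= window_length,
            overlap >= 0, overlap < window_length, frame_rate > 0)
  structure(list(window_length = as.integer(window_length),
                 overlap = as.integer(overlap), n_fft = as.integer(n_fft),
                 frame_rate = frame_rate,
                 window = hamming_window(as.integer(window_length))),
            class = "welch_spec")
}

# Symmetric Hamming window of length n (MATLAB hamming()).
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

welch_freqs <- function(spec) {
  (0:(spec$n_fft %/% 2)) * spec$frame_rate / spec$n_fft
}

n_segments <- function(n, spec) {
  step <- spec$window_length - spec$overlap
  (n - spec$overlap) %/% step
}

# One-sided tapered segment DFTs of the columns of X (time x series).
# The mean of each full series is removed first, so a constant offset never
# leaks through the taper. Returns a complex array (n_freq, n_seg, n_series).
segment_spectra <- function(X, spec) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < spec$window_length)
    stopf("series of length %d shorter than one Welch window (%d)",
          n, spec$window_length)
  ns <- n_segments(n, spec)
  if (ns < 1) stopf("no complete Welch segment fits the series")
  step <- spec$window_length - spec$overlap
  X <- sweep(X, 2L, colMeans(X), "-")
  nf <- spec$n_fft %/% 2L + 1L
  out <- array(0i, dim = c(nf, ns, ncol(X)))
  pad <- spec$n_fft - spec$window_length
  for (s in seq_len(ns)) {
    seg <- X[(s - 1L) * step + seq_len(spec$window_length), , drop = FALSE] *
      spec$window
    if (pad > 0) seg <- rbind(seg, matrix(0, pad, ncol(seg)))
    f <- stats::mvfft(seg)
    out[, s, ] <- f[seq_len(nf), ]
  }
  out
}

# Density normalization: one-sided PSD scale so that the integral of the
# PSD over frequency approximates the series variance.
welch_scale <- function(spec) 1 / (spec$frame_rate * sum(spec$window^2))

one_sided_double <- function(P, spec) {
  nf <- spec$n_fft %/% 2L + 1L
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (spec$n_fft %% 2L == 0L) dbl[nf] <- 1
  P * dbl
}

#' Welch power spectral density
#'
#' One-sided PSD of a single time series by Welch's method ('density'
#' normalization: integrating the PSD over frequency recovers the series
#' variance, up to taper-induced leakage).
#'
#' @param x numeric time series.
#' @param spec a [welch_spec()].
#' @return A list with `freqs` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, spec = welch_spec()) {
  S <- segment_spectra(matrix(x, ncol = 1), spec)
  P <- rowMeans(abs(S[, , 1, drop = FALSE])^2) * welch_scale(spec)
  list(freqs = welch_freqs(spec), psd = one_sided_double(P, spec))
}

#' Welch cross-power spectral density
#'
#' Segment-averaged cross spectrum of two equally long series, with the
#' same taper and normalization as [welch_psd()]. Convention:
#' `P_xy(f) = <X(f) conj(Y(f))>`, so that `y(t) = x(t - tau)` gives
#' `Arg P_xy = +2 pi f tau` at a tone.
#'
#' @param x,y numeric time series of equal length.
#' @param spec a [welch_spec()].
#' @return A list with `freqs` (Hz) and `cross` (complex).
#' @export
cross_spectrum <- function(x, y, spec = welch_spec()) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  S <- segment_spectra(cbind(x, y), spec)
  P <- rowMeans(S[, , 1, drop = FALSE] * Conj(S[, , 2, drop = FALSE])) *
    welch_scale(spec)
  list(freqs = welch_freqs(spec), cross = one_sided_double(P, spec))
}

#' Magnitude-squared coherence
#'
#' `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))`, the frequency-resolved,
#' lag-independent synchronization score in `[0, 1]`. At least two Welch
#' segments are required: a single segment yields the degenerate estimate
#' `C == 1` at all frequencies and is rejected. Frequencies at which either
#' series has exactly zero power have undefined coherence; they are
#' reported as 0 and flagged in the `undefined` attribute.
#'
#' @param x,y numeric time series of equal length.
#' @param spec a [welch_spec()].
#' @return A list with `freqs` (Hz) and `coherence` in `[0, 1]` (attribute
#'   `undefined`: logical, bins where coherence is 0/0).
#' @export
msc <- function(x, y, spec = welch_spec()) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (n_segments(length(x), spec) < 2)
    stopf(paste0("coherence needs at least 2 Welch segments ",
                 "(single-segment coherence is identically 1)"))
  S <- segment_spectra(cbind(x, y), spec)
  Pxx <- rowMeans(abs(S[, , 1, drop = FALSE])^2)
  Pyy <- rowMeans(abs(S[, , 2, drop = FALSE])^2)
  Pxy <- rowMeans(S[, , 1, drop = FALSE] * Conj(S[, , 2, drop = FALSE]))
  denom <- Pxx * Pyy
  C <- numeric(length(denom))
  ok <- denom > 0
  C[ok] <- Mod(Pxy[ok])^2 / denom[ok]
  C <- pmin(pmax(C, 0), 1)
  structure(list(freqs = welch_freqs(spec), coherence = C),
            undefined = !ok)
}
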