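# Independent oracles: deliberately naive re-implementations (explicit
# loops, O(N^2) DFTs) used to pin down the fast paths.

# One-sided DFT of the mean-subtracted series, O(N^2).
naive_dft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nf <- n %/% 2 + 1
  vapply(0:(nf - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

naive_hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Welch auto-/cross-spectra by explicit segment loop + naive DFT.
# Returns the segment-averaged raw (unscaled) spectra.
naive_welch_raw <- function(x, y, wl = 100L, ov = 80L) {
  w <- naive_hamming(wl)
  step <- wl - ov
  ns <- (length(x) - ov) %/% step
  x <- x - mean(x); y <- y - mean(y)
  nf <- wl %/% 2 + 1
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  dftm <- exp(-2i * pi * outer(0:(nf - 1), 0:(wl - 1)) / wl)
  for (s in seq_len(ns)) {
    idx <- (s - 1) * step + seq_len(wl)
    X <- dftm %*% (x[idx] * w)
    Y <- dftm %*% (y[idx] * w)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  list(Sxx = Sxx / ns, Syy = Syy / ns, Sxy = Sxy / ns)
}

naive_msc <- function(x, y, wl = 100L, ov = 80L) {
  s <- naive_welch_raw(x, y, wl, ov)
  Mod(s$Sxy)^2 / (s$Sxx * s$Syy)
}

# Block means by double loop.
naive_block_mean <- function(frame, f) {
  nr <- nrow(frame) %/% f
  nc <- ncol(frame) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- mean(frame[((i - 1) * f + 1):(i * f),
                            ((j - 1) * f + 1):(j * f)])
  }
  out
}

# Smallest absolute angular difference in degrees.
ang_diff_deg <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# Counter-clockwise quarter-turn of a matrix / of every frame of a stack.
rot_ccw <- function(M) t(M)[ncol(M):1, , drop = FALSE]
rot_ccw_stack <- function(stack) {
  d <- dim(stack)
  out <- array(0, c(d[1], d[3], d[2]))
  for (t in seq_len(d[1])) out[t, , ] <- rot_ccw(stack[t, , ])
  out
}

# Single full-field plane-wave scene at analysis scale.
plane_wave_scene <- function(theta, lambda, seed, shape = c(48L, 48L),
                             frames = 800L, f = 25, jitter = 0.2,
                             noise_sd = 0.2, amplitude = 1) {
  scene_spec(list(patch_spec(c(1, 1, shape[1], shape[2]), f,
                             amplitude = amplitude, theta = theta,
                             wavelength = lambda,
                             phase_jitter_sd = jitter)),
             frame_count = frames, frame_rate = 100, shape = shape,
             pixel_size = 0.75, pixel_noise_sd = noise_sd, seed = seed)
}

# Run the analysis chain on a recording already at analysis scale.
analyse_scene <- function(g, ...) {
  run_pipeline(g$recording, config = pipeline_config(downsample = 1, ...))
}
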