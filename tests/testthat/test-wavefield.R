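# A hand-built patch map covering the full field, for driving the phase /
# gradient operators directly.
full_patch_map <- function(nr, nc, dominant_freq = 25, px = 0.75) {
  structure(list(
    labels = matrix(1L, nr, nc), n_patches = 1L, bin_width = 0.5,
    patches = data.frame(label = 1L, n_pixels = nr * nc, bin_lo = 25,
                         bin_hi = 25.5, bin_freq = 25.25,
                         dominant_freq = dominant_freq),
    pixel_size = px), class = "cilia_patches")
}

phase_map_of <- function(phi, px = 0.75) {
  map_image(phi, units = "rad", pixel_size = px)
}

test_that("phase_map reads the initial phase of on-grid cosines", {
  n <- 800; fs <- 100
  t_axis <- (0:(n - 1)) / fs
  phi0 <- c(0.4, -2.0, 3.0, 1.2)
  stack <- array(0, dim = c(n, 2, 2))
  for (i in 1:4) stack[, (i - 1) %% 2 + 1, (i - 1) %/% 2 + 1] <-
    cos(2 * pi * 25 * t_axis + phi0[i])
  rec <- recording(stack, fs, 0.75)
  sp <- pixel_spectra(rec, min_frames = 200L)
  ph <- phase_map(sp, full_patch_map(2, 2))
  expect_equal(as.vector(ph$values), phi0, tolerance = 1e-8)
  # pairwise lags are preserved
  expect_equal(ph$values[2, 1] - ph$values[1, 1], phi0[2] - phi0[1],
               tolerance = 1e-8)
})

test_that("phase_map recovers generator plane-wave phase fields", {
  g <- generate_recording(plane_wave_scene(30, 15, seed = 21, jitter = 0,
                                           noise_sd = 0, shape = c(24L, 24L),
                                           frames = 400L))
  sp <- pixel_spectra(g$recording, min_frames = 200L)
  ph <- phase_map(sp, full_patch_map(24, 24))
  d <- ciliakit:::wrap_pi(ph$values - g$phase)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("circular_gradient is exact for plane waves, including across the seam", {
  nr <- 20; nc <- 20; px <- 0.75
  k <- c(0.12, -0.3)  # rad/um
  xy_phi <- function(offset) {
    outer(seq_len(nr), seq_len(nc), function(r, c)
      ciliakit:::wrap_pi(k[1] * c * px + k[2] * r * px + offset))
  }
  pm <- full_patch_map(nr, nc)
  g0 <- circular_gradient(phase_map_of(xy_phi(0)), pm)
  inner <- as.vector(!is.na(g0$gx))
  expect_true(any(inner))
  expect_equal(g0$gx[!is.na(g0$gx)], rep(k[1], sum(!is.na(g0$gx))),
               tolerance = 1e-10)
  expect_equal(g0$gy[!is.na(g0$gy)], rep(k[2], sum(!is.na(g0$gy))),
               tolerance = 1e-10)
  # shifting the field so the wrap seam crosses the patch changes nothing
  g_seam <- circular_gradient(phase_map_of(xy_phi(pi - 0.05)), pm)
  expect_equal(g_seam$gx, g0$gx, tolerance = 1e-10)
  expect_equal(g_seam$gy, g0$gy, tolerance = 1e-10)

  # constant phase: zero gradient
  gc <- circular_gradient(phase_map_of(matrix(1.5, nr, nc)), pm)
  expect_true(all(gc$magnitude[!is.na(gc$magnitude)] == 0))

  # border/patch-edge pixels are dropped
  expect_true(all(is.na(g0$gx[1, ])))
  expect_true(all(is.na(g0$gx[, nc])))
})

test_that("wave_direction takes circular means and flags dispersed patches", {
  nr <- 20; nc <- 20; px <- 0.75
  pm <- full_patch_map(nr, nc)
  # gradient pointing 45 deg up-left in propagation terms: build from a
  # plane wave with known theta
  kv <- angle_to_wavevector(45, 20)
  phi <- outer(seq_len(nr), seq_len(nc), function(r, c)
    ciliakit:::wrap_pi(-(kv$kx * c * px + kv$ky * r * px)))
  wd <- wave_direction(circular_gradient(phase_map_of(phi), pm))
  expect_equal(wd$mean_direction_deg, 45, tolerance = 1e-6)
  expect_equal(wd$circular_sd, 0, tolerance = 1e-6)
  expect_false(wd$low_confidence)

  # gradients uniform on the circle: tiny resultant, large circular SD
  set.seed(22)
  fake <- structure(list(
    gx = matrix(cos(runif(400, 0, 2 * pi)), 20, 20),
    gy = matrix(sin(runif(400, 0, 2 * pi)), 20, 20),
    labels = matrix(1L, 20, 20), n_patches = 1L, pixel_size = px),
    class = "cilia_gradient")
  fake$magnitude <- sqrt(fake$gx^2 + fake$gy^2)
  fake$direction <- atan2(fake$gy, fake$gx)
  wd2 <- wave_direction(fake)
  expect_gt(wd2$circular_sd, 1.5)

  # fewer than min_pixels valid gradients: flagged
  tiny <- structure(list(gx = matrix(c(1, rep(NA, 24)), 5, 5),
                         gy = matrix(c(0, rep(NA, 24)), 5, 5),
                         labels = matrix(c(1L, rep(0L, 24)), 5, 5),
                         n_patches = 1L, pixel_size = px),
                    class = "cilia_gradient")
  tiny$magnitude <- sqrt(tiny$gx^2 + tiny$gy^2)
  tiny$direction <- atan2(tiny$gy, tiny$gx)
  expect_true(wave_direction(tiny)$low_confidence)
})

test_that("wavelength estimators: mean vector, modal magnitude, caps", {
  nr <- 30; nc <- 30; px <- 0.75
  pm <- full_patch_map(nr, nc)
  kv <- angle_to_wavevector(120, 20)
  phi <- outer(seq_len(nr), seq_len(nc), function(r, c)
    ciliakit:::wrap_pi(-(kv$kx * c * px + kv$ky * r * px)))
  grad <- circular_gradient(phase_map_of(phi), pm)
  expect_equal(wavelength(grad, method = "mean_vector")$wavelength_um, 20,
               tolerance = 0.01)
  # mode: within one 0.01 rad/um magnitude bin of the truth
  lam_mode <- wavelength(grad, method = "mode")$wavelength_um
  k_true <- 2 * pi / 20
  expect_lt(abs(2 * pi / lam_mode - k_true), 0.01)

  # constant phase: capped, flagged
  gc <- circular_gradient(phase_map_of(matrix(0.3, nr, nc)), pm)
  for (m in c("mean_vector", "mode")) {
    wl <- wavelength(gc, method = m)
    expect_true(wl$capped)
    expect_equal(wl$wavelength_um, 2 * pi / 0.01)
  }

  # 70/30 mixture of 10 um and 40 um: the mode picks the majority, not a blend
  n_tot <- 1000
  mags <- c(rep(2 * pi / 10, 700), rep(2 * pi / 40, 300))
  fake <- structure(list(
    gx = matrix(mags, 25, 40), gy = matrix(0, 25, 40),
    labels = matrix(1L, 25, 40), n_patches = 1L, pixel_size = px),
    class = "cilia_gradient")
  fake$magnitude <- abs(fake$gx)
  fake$direction <- atan2(fake$gy, fake$gx)
  expect_equal(wavelength(fake, method = "mode")$wavelength_um, 10,
               tolerance = 0.1)
})

test_that("end-to-end recovery, rotation equivariance and phase-origin invariance", {
  g <- generate_recording(plane_wave_scene(30, 20, seed = 23))
  res <- analyse_scene(g)
  expect_equal(res$patches$n_patches, 1)
  expect_lt(ang_diff_deg(res$waves$mean_direction_deg, 30), 2)
  expect_lt(abs(res$waves$wavelength_um - 20) / 20, 0.05)

  # rotating the stack 90 deg CCW rotates the direction by -90 deg and
  # leaves the wavelength unchanged
  rot <- recording(rot_ccw_stack(g$recording$stack), 100, 0.75)
  res_rot <- analyse_scene(list(recording = rot))
  expect_lt(ang_diff_deg(res_rot$waves$mean_direction_deg,
                         res$waves$mean_direction_deg - 90), 0.5)
  expect_lt(abs(res_rot$waves$wavelength_um - res$waves$wavelength_um), 0.3)

  # a global phase offset (Fourier phase origin) changes neither direction
  # dispersion nor wavelength: shift the whole recording by two frames
  sh <- g$recording$stack[c(3:800, 1:2), , ]
  res_sh <- analyse_scene(list(recording = recording(sh, 100, 0.75)))
  expect_equal(res_sh$waves$circular_sd, res$waves$circular_sd,
               tolerance = 0.05)
  expect_lt(ang_diff_deg(res_sh$waves$mean_direction_deg,
                         res$waves$mean_direction_deg), 0.5)
})
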