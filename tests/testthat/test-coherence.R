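spec100 <- welch_spec(100L, 80L, 100L, frame_rate = 100)

test_that("welch_psd integrates to the variance and localizes tones", {
  set.seed(6)
  x <- rnorm(3000)
  p <- welch_psd(x, spec100)
  df <- p$freqs[2] - p$freqs[1]
  expect_equal(sum(p$psd) * df, 1, tolerance = 0.05)

  tone <- generate_pair(25, n = 3000)$x
  pt <- welch_psd(tone, spec100)
  expect_equal(pt$freqs[which.max(pt$psd)], 25)
  expect_gt(max(pt$psd) / sum(pt$psd), 0.3)

  # linearity: a*x scales the density by a^2
  pa <- welch_psd(3 * x, spec100)
  expect_equal(pa$psd, 9 * p$psd, tolerance = 1e-12)
  expect_error(welch_psd(rnorm(50), spec100), "shorter")
})

test_that("cross_spectrum is Hermitian and carries the lag phase", {
  set.seed(7)
  x <- rnorm(1000); y <- rnorm(1000)
  cxx <- cross_spectrum(x, x, spec100)$cross
  expect_true(all(abs(Im(cxx)) < 1e-12))
  expect_true(all(Re(cxx) >= 0))
  cxy <- cross_spectrum(x, y, spec100)$cross
  cyx <- cross_spectrum(y, x, spec100)$cross
  expect_equal(cxy, Conj(cyx), tolerance = 1e-12)

  # y = x delayed by tau: Arg P_xy(f) = 2 pi f tau
  fs <- 100; f0 <- 20; tau <- 3 / fs
  t_axis <- (0:1499) / fs
  xt <- cos(2 * pi * f0 * t_axis)
  yt <- cos(2 * pi * f0 * (t_axis - tau))
  cs <- cross_spectrum(xt, yt, spec100)
  i0 <- which(cs$freqs == f0)
  expect_equal(Arg(cs$cross[i0]), ciliakit:::wrap_pi(2 * pi * f0 * tau),
               tolerance = 1e-6)
  expect_error(cross_spectrum(x, y[-1], spec100), "equal length")
})

test_that("msc matches the naive segment-loop oracle", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(500); y <- 0.5 * x + rnorm(500)
    ours <- msc(x, y, spec100)$coherence
    expect_lt(max(abs(ours - naive_msc(x, y))), 1e-8)
  }
})

test_that("msc contracts: self-coherence, bounds, symmetry, invariances", {
  set.seed(9)
  x <- rnorm(1000)
  expect_equal(msc(x, x, spec100)$coherence, rep(1, 51), tolerance = 1e-10)

  pair <- generate_pair(25, lag = pi / 3, snr = 10, n = 3000, seed = 1)
  C <- msc(pair$x, pair$y, spec100)
  expect_true(all(C$coherence >= 0 & C$coherence <= 1))
  expect_gte(C$coherence[C$freqs == 25], 0.9)

  # symmetry and affine invariance
  y <- pair$y
  expect_equal(msc(pair$x, y, spec100)$coherence,
               msc(y, pair$x, spec100)$coherence, tolerance = 1e-12)
  expect_equal(msc(2.3 * pair$x - 7, 0.4 * y + 100, spec100)$coherence,
               C$coherence, tolerance = 1e-9)

  # lag invariance for identical tones: coherence at the tone is 1 for any lag
  for (lag in c(0, pi / 3, 2)) {
    p <- generate_pair(25, lag = lag, n = 1000)
    expect_equal(msc(p$x, p$y, spec100)$coherence[26], 1, tolerance = 1e-9)
  }

  # independent noise: mean coherence near 1/n_segments, well below 0.2
  z1 <- rnorm(3000); z2 <- rnorm(3000)
  expect_lt(mean(msc(z1, z2, spec100)$coherence), 0.2)

  # degenerate inputs
  expect_error(msc(rnorm(110), rnorm(110), spec100), "2 Welch segments")
  flat <- rep(0, 1000)
  res <- msc(flat, rnorm(1000), spec100)
  expect_true(all(res$coherence == 0))
  expect_true(all(attr(res, "undefined")))
})

test_that("per-segment random lag destroys coherence but not frequency content", {
  p <- generate_pair(25, snr = 10, n = 3000, seed = 2, per_segment_lag = TRUE)
  C <- msc(p$x, p$y, spec100)
  expect_lt(C$coherence[C$freqs == 25], 0.3)
  py <- welch_psd(p$y, spec100)
  expect_equal(py$freqs[which.max(py$psd)], 25)
})

test_that("coherence_map separates synchronized, coincident and noise pixels", {
  # top patch: coherent plane wave; bottom patch: same frequency, incoherent
  sp <- scene_spec(list(
    patch_spec(c(3, 3, 14, 30), 25, theta = 90, wavelength = 20),
    patch_spec(c(19, 3, 30, 30), 25, incoherent = TRUE)),
    frame_count = 2000, shape = c(32L, 32L), pixel_size = 0.75,
    pixel_noise_sd = 0.2, seed = 11)
  g <- generate_recording(sp)
  res <- coherence_map(g$recording, reference = c(8, 16))
  expect_equal(res$peak_coherence$values[8, 16], 1)
  expect_equal(res$reference$cbf, 25)

  coh <- res$peak_coherence$values
  pow <- res$power_at_ref$values
  top <- g$labels == 1L; bottom <- g$labels == 2L; bg <- g$labels == 0L
  expect_gte(stats::median(coh[top]), 0.9)
  expect_lt(stats::median(coh[bg]), 0.2)
  # the incoherent patch shares the reference frequency but not its phase
  expect_gte(stats::median(pow[bottom]), 25)
  expect_lt(stats::median(coh[bottom]), 0.3)

  cls <- classify_pixels(res)
  expect_equal(as.character(stats::na.omit(unique(cls[top]))[1]), "synchronized")
  tab_top <- table(cls[top])
  expect_gt(tab_top[["synchronized"]] / sum(top), 0.5)
  tab_bot <- table(cls[bottom])
  expect_gt(tab_bot[["same_freq_unsynchronized"]] / sum(bottom), 0.5)
  expect_error(coherence_map(g$recording, reference = c(8, 16),
                             mask = matrix(FALSE, 32, 32)),
               "outside the signal mask")
})

test_that("classify_pixels applies the coherence/power thresholds", {
  fake <- structure(list(
    peak_coherence = map_image(matrix(c(0.9, 0.1, 0.4, 0.4), 2, 2),
                               "dimensionless"),
    power_at_ref = map_image(matrix(c(40, 30, 18, 30), 2, 2), "percent")),
    class = "cilia_coherence")
  cls <- classify_pixels(fake)
  expect_equal(as.character(cls[1, 1]), "synchronized")
  expect_equal(as.character(cls[2, 1]), "same_freq_unsynchronized")
  # low power, moderate coherence: the "different frequency" box
  expect_equal(as.character(cls[1, 2]), "different_freq")
  # moderate coherence but too much power for green, too little for red/blue
  expect_equal(as.character(cls[2, 2]), "other")
})

test_that("coherence_vs_distance accumulates sane histograms", {
  # all pixels share one series: coherence 1 everywhere
  n <- 600
  base <- generate_pair(25, snr = 20, n = n, seed = 3)$x
  stack <- array(rep(base, times = 36), dim = c(n, 6, 6))
  rec <- recording(stack, 100, 0.75)
  h <- coherence_vs_distance(rec, n_pairs = 200, seed = 1)
  expect_equal(h$n_pairs_sampled, 200)
  expect_equal(sum(h$counts), 200)
  occupied <- which(!is.na(h$mean_per_distance))
  expect_true(all(h$mean_per_distance[occupied] > 0.999))
  expect_true(all(h$fraction_above_threshold[occupied] == 1))

  # a coherent patch in an incoherent surround: coherence decays with distance
  sp <- scene_spec(list(
    patch_spec(c(1, 1, 20, 20), 25, theta = 0, wavelength = 30)),
    frame_count = 800, shape = c(40L, 40L), pixel_size = 0.75,
    pixel_noise_sd = 0.5, seed = 12)
  g <- generate_recording(sp)
  h2 <- coherence_vs_distance(g$recording, n_pairs = 4000, seed = 2)
  d_mid <- (h2$distance_edges[-1] + utils::head(h2$distance_edges, -1)) / 2
  near <- d_mid <= 10 & !is.na(h2$mean_per_distance)
  far <- d_mid >= 25 & !is.na(h2$mean_per_distance)
  expect_gt(mean(h2$mean_per_distance[near]), mean(h2$mean_per_distance[far]))
  expect_error(coherence_vs_distance(rec, mask = matrix(FALSE, 6, 6)),
               "at least 2")
})
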