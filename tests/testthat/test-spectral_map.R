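make_rec <- function(stack, fs = 100, px = 0.15) recording(stack, fs, px)

test_that("downsample_stack block-averages and rescales pixel size", {
  set.seed(1)
  stack <- array(rnorm(3 * 25 * 25), dim = c(3, 25, 25))
  rec <- make_rec(stack)
  expect_identical(downsample_stack(rec, 1L), rec)

  const <- make_rec(array(7, dim = c(2, 10, 10)))
  small <- downsample_stack(const, 5L)
  expect_identical(dim(small$stack), c(2L, 2L, 2L))
  expect_true(all(small$stack == 7))
  expect_equal(small$pixel_size, 0.15 * 5)

  ds <- downsample_stack(rec, 5L)
  for (t in 1:3)
    expect_equal(ds$stack[t, , ], naive_block_mean(stack[t, , ], 5L))

  # trailing partial blocks dropped
  odd <- downsample_stack(make_rec(array(rnorm(2 * 27 * 26), c(2, 27, 26))), 5L)
  expect_identical(dim(odd$stack), c(2L, 5L, 5L))
  expect_error(downsample_stack(rec, 0), "positive integer")
})

test_that("pixel_spectra matches a naive DFT and obeys Parseval", {
  set.seed(2)
  n <- 300
  stack <- array(rnorm(n * 3 * 3), dim = c(n, 3, 3))
  t_axis <- (0:(n - 1)) / 100
  stack[, 1, 1] <- cos(2 * pi * 25 * t_axis)
  stack[, 2, 2] <- 5
  sp <- pixel_spectra(make_rec(stack), min_frames = 200L)

  expect_equal(sp$freqs[1], 0)
  expect_equal(max(sp$freqs), 50)
  expect_identical(dim(sp$coefficients), c(151L, 3L, 3L))

  # on-grid tone peaks exactly at 25 Hz
  mag <- abs(sp$coefficients[, 1, 1])
  expect_equal(sp$freqs[which.max(mag)], 25)
  # constant pixel: all coefficients zero
  expect_true(all(abs(sp$coefficients[, 2, 2]) < 1e-9))

  for (rc in list(c(1, 2), c(3, 3), c(2, 1))) {
    ours <- sp$coefficients[, rc[1], rc[2]]
    ref <- naive_dft(stack[, rc[1], rc[2]])
    expect_lt(max(abs(ours - ref)) / max(abs(ref)), 1e-8)
  }

  # Parseval (one-sided weighting): sum w_k |X_k|^2 / N = var * N / N
  x <- stack[, 3, 1]
  w <- rep(2, n %/% 2 + 1); w[1] <- 1; if (n %% 2 == 0) w[n %/% 2 + 1] <- 1
  lhs <- sum(w * abs(sp$coefficients[, 3, 1])^2) / n
  rhs <- sum((x - mean(x))^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("peak_frequency_map restricts to the band and is affine-invariant", {
  n <- 400
  t_axis <- (0:(n - 1)) / 100
  stack <- array(0, dim = c(n, 2, 2))
  stack[, 1, 1] <- cos(2 * pi * 25 * t_axis)
  stack[, 1, 2] <- 2 * cos(2 * pi * 10 * t_axis) + cos(2 * pi * 30 * t_axis)
  set.seed(3)
  stack[, 2, 1] <- rnorm(n)
  stack[, 2, 2] <- rnorm(n)
  rec <- make_rec(stack)
  sp <- pixel_spectra(rec, min_frames = 200L)
  fm <- peak_frequency_map(sp, f_min = 15, f_max = 50)

  expect_equal(fm$values[1, 1], 25)
  # the stronger 10 Hz tone is outside the band
  expect_equal(fm$values[1, 2], 30)
  # white noise: brute-force argmax over the band
  sel <- which(sp$freqs >= 15 & sp$freqs <= 50)
  for (rc in list(c(2, 1), c(2, 2))) {
    ref <- naive_dft(stack[, rc[1], rc[2]])
    expect_equal(fm$values[rc[1], rc[2]], sp$freqs[sel[which.max(abs(ref[sel]))]])
  }
  # affine intensity rescaling leaves the map unchanged
  fm2 <- peak_frequency_map(pixel_spectra(make_rec(3.7 * stack + 11),
                                          min_frames = 200L), 15, 50)
  expect_equal(fm2$values, fm$values)
  expect_error(peak_frequency_map(sp, 40, 20), "f_min < f_max")
})

test_that("signal_mask keeps locally frequency-stable regions only", {
  uni <- map_image(matrix(25, 100, 100), units = "Hz", pixel_size = 0.75)
  m <- signal_mask(uni, min_region = 500L)
  expect_true(all(m$mask))

  set.seed(4)
  noisy <- map_image(matrix(runif(1e4, 15, 50), 100, 100), units = "Hz",
                     pixel_size = 0.75)
  expect_equal(sum(signal_mask(noisy, min_region = 500L)$mask), 0)

  # 30x30 uniform square inside a random background
  vals <- matrix(runif(1e4, 15, 50), 100, 100)
  vals[31:60, 31:60] <- 25
  emb <- map_image(vals, units = "Hz", pixel_size = 0.75)
  m3 <- signal_mask(emb, min_region = 500L)
  expect_true(all(m3$mask[31:60, 31:60]))
  lab <- ciliakit:::label_components(m3$mask, 8L)
  expect_equal(max(lab), 1)              # no surviving background component
  expect_lt(sum(m3$mask), 1.3 * 900)

  # monotone in min_region
  m_lo <- signal_mask(emb, min_region = 100L)
  expect_true(all(m3$mask <= m_lo$mask))
  expect_error(signal_mask(uni, kernel = 4L), "odd")
})
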