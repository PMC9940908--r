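# Reference-pixel coherence maps, pixel classification, and the
# coherence-versus-distance statistics.

#' Coherence map against a reference pixel
#'
#' For every signal pixel, the magnitude-squared coherence with a chosen
#' reference pixel is estimated by Welch's method and reduced to its peak
#' over a frequency band (default 15 Hz to Nyquist). Alongside, the
#' spectral power of each pixel at the reference pixel's beat frequency is
#' reported as a percentage of that pixel's total band power — high power
#' with low coherence identifies cilia that share a frequency by
#' coincidence without being synchronized.
#'
#' @param rec a [recording()], already at analysis scale (downsample first
#'   if desired).
#' @param reference `c(row, col)` of the reference pixel (must be in the
#'   mask).
#' @param mask boolean matrix or [map_image()] of signal pixels; `NULL`
#'   analyses every pixel.
#' @param spec a [welch_spec()]; its `frame_rate` is taken from `rec`.
#' @param band `c(f_min, f_max)` Hz over which the coherence peak and the
#'   total power are taken.
#' @param reduction `"peak"` (max coherence over the band) or `"at_ref"`
#'   (coherence at the reference beat frequency line).
#' @param block pixels per processing block (memory/speed knob).
#' @return An object of class `cilia_coherence`: `peak_coherence` and
#'   `power_at_ref` ([map_image()]s), `reference` (row, col, `cbf` on the
#'   Welch grid), `band`, `spec`.
#' @export
coherence_map <- function(rec, reference, mask = NULL, spec = NULL,
                          band = NULL, reduction = c("peak", "at_ref"),
                          block = 2048L) {
  stopifnot(inherits(rec, "cilia_recording"))
  reduction <- match.arg(reduction)
  d <- dim(rec$stack)
  if (is.null(spec)) spec <- welch_spec(frame_rate = rec$frame_rate)
  spec$frame_rate <- rec$frame_rate
  if (is.null(band)) band <- c(15, rec$frame_rate / 2)
  if (inherits(mask, "cilia_map")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  stopifnot(identical(dim(mask), d[2:3]))
  r0 <- as.integer(reference[1]); c0 <- as.integer(reference[2])
  if (r0 < 1 || r0 > d[2] || c0 < 1 || c0 > d[3] || !mask[r0, c0])
    stopf("reference pixel (%d, %d) is outside the signal mask", r0, c0)

  X <- rec$stack
  dim(X) <- c(d[1], d[2] * d[3])
  freqs <- welch_freqs(spec)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0) stopf("no Welch line in the band [%g, %g] Hz",
                              band[1], band[2])
  ref_idx <- (c0 - 1L) * d[2] + r0
  Sr <- segment_spectra(X[, ref_idx, drop = FALSE], spec)[, , 1]
  ns <- ncol(Sr)
  if (ns < 2) stopf("recording too short for a coherence estimate")
  Pr <- rowMeans(abs(Sr)^2)
  ref_line <- sel[which.max(Pr[sel])]
  ref_cbf <- freqs[ref_line]

  pix <- which(mask)
  coh <- matrix(NA_real_, d[2], d[3])
  pow <- matrix(NA_real_, d[2], d[3])
  cSr <- as.vector(Conj(Sr))
  for (start in seq(1L, length(pix), by = block)) {
    ii <- pix[start:min(start + block - 1L, length(pix))]
    S <- segment_spectra(X[, ii, drop = FALSE], spec)
    nb <- dim(S)[3]
    Pp <- colSums(aperm(abs(S)^2, c(2, 1, 3)), dims = 1) / ns  # n_freq x nb
    dim(S) <- c(length(cSr), nb)
    cross <- cSr * S
    dim(cross) <- c(length(freqs), ns, nb)
    num <- colSums(aperm(cross, c(2, 1, 3)), dims = 1) / ns  # n_freq x nb
    C <- Mod(num)^2 / outer(Pr, rep(1, nb)) / Pp
    C[!is.finite(C)] <- 0
    C <- pmin(pmax(C, 0), 1)
    coh[ii] <- if (reduction == "peak") {
      apply(C[sel, , drop = FALSE], 2, max)
    } else C[ref_line, ]
    tot <- colSums(Pp[sel, , drop = FALSE])
    pow[ii] <- ifelse(tot > 0, 100 * Pp[ref_line, ] / tot, 0)
  }
  structure(
    list(peak_coherence = map_image(coh, "dimensionless", mask = mask,
                                    pixel_size = rec$pixel_size),
         power_at_ref = map_image(pow, "percent", mask = mask,
                                  pixel_size = rec$pixel_size),
         reference = list(row = r0, col = c0, cbf = ref_cbf),
         band = band, spec = spec, reduction = reduction),
    class = "cilia_coherence")
}

#' @export
print.cilia_coherence <- function(x, ...) {
  cat(sprintf(
    "<cilia_coherence> reference (%d, %d) @ %.4g Hz, band [%g, %g] Hz\n",
    x$reference$row, x$reference$col, x$reference$cbf, x$band[1], x$band[2]))
  invisible(x)
}

#' Classify pixels by coherence and spectral power
#'
#' Reproduces the coherence/power quadrant logic used to separate
#' synchronized from coincidentally same-frequency cilia:
#' * `synchronized` ("red"): coherence >= 0.5 and power >= 10%
#' * `same_freq_unsynchronized` ("blue"): coherence <= 0.3 and power >= 25%
#' * `different_freq` ("green"): coherence <= 0.5 and power <= 25%
#' * `other`: everything else.
#' Classes are assigned in that priority order (the blue and green boxes
#' share only their power = 25% boundary).
#'
#' @param result a [coherence_map()] result.
#' @return A factor matrix (levels above), `NA` outside the mask.
#' @export
classify_pixels <- function(result) {
  stopifnot(inherits(result, "cilia_coherence"))
  C <- result$peak_coherence$values
  P <- result$power_at_ref$values
  cls <- matrix(NA_character_, nrow(C), ncol(C))
  ok <- result$peak_coherence$mask
  cls[ok] <- "other"
  cls[ok & C <= 0.5 & P <= 25] <- "different_freq"
  cls[ok & C <= 0.3 & P >= 25] <- "same_freq_unsynchronized"
  cls[ok & C >= 0.5 & P >= 10] <- "synchronized"
  out <- factor(cls, levels = c("synchronized", "same_freq_unsynchronized",
                                "different_freq", "other"))
  dim(out) <- dim(C)
  out
}

#' Coherence versus pixel distance
#'
#' Estimates how synchronization decays with distance: for a random
#' subsample of unordered signal-pixel pairs, the peak band coherence and
#' the Euclidean pixel distance (in micrometres) are accumulated into a 2-D
#' histogram (0.5 um distance bins x 0.04 coherence bins), together with
#' the per-distance-bin mean coherence and the fraction of pairs above a
#' coherence threshold (default 0.25).
#'
#' @inheritParams coherence_map
#' @param n_pairs number of pair draws (uniform over unordered distinct
#'   pairs, drawn with replacement); `Inf` enumerates all pairs.
#' @param seed RNG seed for the pair subsample.
#' @param distance_bin um, histogram bin width for distance.
#' @param coherence_bin histogram bin width for coherence.
#' @param threshold coherence level defining a "coherent" pair.
#' @return An object of class `cilia_cohdist`: `distance_edges`,
#'   `coherence_edges`, `counts` (distance x coherence), `mean_per_distance`,
#'   `fraction_above_threshold`, `n_pairs_sampled`.
#' @export
coherence_vs_distance <- function(rec, mask = NULL, spec = NULL, band = NULL,
                                  n_pairs = 2e5, seed = 1L,
                                  distance_bin = 0.5, coherence_bin = 0.04,
                                  threshold = 0.25, block = 512L) {
  stopifnot(inherits(rec, "cilia_recording"))
  d <- dim(rec$stack)
  if (is.null(spec)) spec <- welch_spec(frame_rate = rec$frame_rate)
  spec$frame_rate <- rec$frame_rate
  if (is.null(band)) band <- c(15, rec$frame_rate / 2)
  if (inherits(mask, "cilia_map")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  pix <- which(mask)
  P <- length(pix)
  if (P < 2) stopf("need at least 2 signal pixels")

  X <- rec$stack
  dim(X) <- c(d[1], d[2] * d[3])
  S <- segment_spectra(X[, pix, drop = FALSE], spec)
  nf <- dim(S)[1]; ns <- dim(S)[2]
  if (ns < 2) stopf("recording too short for a coherence estimate")
  freqs <- welch_freqs(spec)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  Pp <- colSums(aperm(abs(S)^2, c(2, 1, 3)), dims = 1) / ns    # nf x P
  dim(S) <- c(nf * ns, P)

  rows <- ((pix - 1L) %% d[2]) + 1L
  cols <- ((pix - 1L) %/% d[2]) + 1L

  all_pairs <- as.numeric(P) * (P - 1) / 2
  if (is.infinite(n_pairs) || n_pairs >= all_pairs) {
    comb <- utils::combn(P, 2L)
    iv <- comb[1, ]; jv <- comb[2, ]
  } else {
    with_seed(seed, {
      iv <- sample.int(P, n_pairs, replace = TRUE)
      jv <- sample.int(P - 1L, n_pairs, replace = TRUE)
      jv <- jv + (jv >= iv)
    })
  }
  n_sampled <- length(iv)
  dist_um <- rec$pixel_size * sqrt((rows[iv] - rows[jv])^2 +
                                   (cols[iv] - cols[jv])^2)
  n_dist <- max(1L, ceiling(max(dist_um) / distance_bin))
  n_coh <- ceiling(1 / coherence_bin)
  counts <- matrix(0L, n_dist, n_coh)
  coh_sum <- numeric(n_dist); coh_n <- numeric(n_dist)
  coh_above <- numeric(n_dist)
  dbin <- pmin(pmax(floor(dist_um / distance_bin), 0), n_dist - 1) + 1L

  for (start in seq(1L, n_sampled, by = block)) {
    kk <- start:min(start + block - 1L, n_sampled)
    nb <- length(kk)
    cross <- Conj(S[, iv[kk], drop = FALSE]) * S[, jv[kk], drop = FALSE]
    dim(cross) <- c(nf, ns, nb)
    num <- colSums(aperm(cross, c(2, 1, 3)), dims = 1) / ns
    C <- Mod(num)^2 / (Pp[, iv[kk], drop = FALSE] * Pp[, jv[kk], drop = FALSE])
    C[!is.finite(C)] <- 0
    pk <- apply(C[sel, , drop = FALSE], 2, max)
    pk <- pmin(pmax(pk, 0), 1)
    cb <- pmin(pmax(floor(pk / coherence_bin), 0), n_coh - 1) + 1L
    db <- dbin[kk]
    for (u in seq_len(nb)) counts[db[u], cb[u]] <- counts[db[u], cb[u]] + 1L
    coh_sum <- coh_sum + as.vector(tapply_add(pk, db, n_dist))
    coh_n <- coh_n + as.vector(tapply_add(rep(1, nb), db, n_dist))
    coh_above <- coh_above + as.vector(tapply_add(as.numeric(pk > threshold),
                                                  db, n_dist))
  }
  structure(
    list(distance_edges = seq(0, n_dist * distance_bin, by = distance_bin),
         coherence_edges = seq(0, n_coh * coherence_bin, by = coherence_bin),
         counts = counts,
         mean_per_distance = ifelse(coh_n > 0, coh_sum / coh_n, NA_real_),
         fraction_above_threshold = ifelse(coh_n > 0, coh_above / coh_n,
                                           NA_real_),
         threshold = threshold, n_pairs_sampled = n_sampled,
         band = band, spec = spec),
    class = "cilia_cohdist")
}

# sum `x` into `n` groups given integer group ids.
tapply_add <- function(x, g, n) {
  out <- numeric(n)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.cilia_cohdist <- function(x, ...) {
  cat(sprintf(
    "<cilia_cohdist> %d pairs, %d distance bins x %d coherence bins\n",
    x$n_pairs_sampled, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
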