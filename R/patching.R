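#' Segment the signal region into same-frequency patches
#'
#' Peak frequencies are quantized into `n_bins` uniform bins spanning
#' `[0, frame_rate/2]` (100 bins at ~108 Hz acquisition gives the 0.54 Hz
#' CBF bin used throughout), and connected components of masked pixels are
#' computed within each bin. Components smaller than `min_patch` pixels are
#' discarded. Patches are numbered `1..n_patches` in raster order of their
#' first (top-left-most) pixel.
#'
#' @param freq_map a [peak_frequency_map()] result (units Hz).
#' @param mask a boolean [map_image()] from [signal_mask()], same geometry.
#' @param frame_rate acquisition rate in Hz, setting the bin range
#'   `[0, frame_rate/2]`.
#' @param n_bins number of uniform frequency bins (>= 2).
#' @param connectivity 4 or 8 (default 8, the standard image neighborhood).
#' @param min_patch smallest surviving patch, in pixels.
#' @return An object of class `cilia_patches`: `labels` (integer matrix,
#'   0 = background), `n_patches`, `bin_width` (Hz), and a data frame
#'   `patches` with `label`, `n_pixels`, `bin_lo`, `bin_hi`, `bin_freq`
#'   (bin center) per patch. Dominant frequencies are added by
#'   [patch_dominant_frequency()].
#' @export
segment_frequency_patches <- function(freq_map, mask, frame_rate,
                                      n_bins = 100L, connectivity = 8L,
                                      min_patch = 200L) {
  stopifnot(inherits(freq_map, "cilia_map"))
  if (inherits(mask, "cilia_map")) mask <- mask$mask
  mask <- as.matrix(mask)
  if (!identical(dim(freq_map$values), dim(mask)))
    stopf("freq_map and mask geometries differ")
  if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be an integer >= 2")
  bin_width <- (frame_rate / 2) / n_bins
  f <- freq_map$values
  bin <- pmin(pmax(floor(f / bin_width), 0), n_bins - 1) + 1L  # 1..n_bins
  labels <- matrix(0L, nrow(f), ncol(f))
  info <- list()
  next_label <- 0L
  for (b in sort(unique(bin[mask]))) {
    comp <- label_components(mask & bin == b, connectivity = as.integer(connectivity))
    if (max(comp) == 0L) next
    sizes <- tabulate(comp[comp > 0L])
    for (k in which(sizes >= min_patch)) {
      next_label <- next_label + 1L
      labels[comp == k] <- next_label
      info[[next_label]] <- data.frame(
        label = next_label, n_pixels = sizes[k],
        bin_lo = (b - 1L) * bin_width, bin_hi = b * bin_width,
        bin_freq = (b - 0.5) * bin_width)
    }
  }
  # renumber in raster order of first pixel (bins were visited by frequency)
  if (next_label > 0L) {
    nr <- nrow(labels); nc <- ncol(labels)
    idx <- which(labels > 0L)
    raster_pos <- (((idx - 1L) %% nr)) * nc + ((idx - 1L) %/% nr) + 1L
    first_pos <- tapply(raster_pos, labels[idx], min)
    ord <- order(first_pos)
    remap <- integer(next_label)
    remap[as.integer(names(first_pos))[ord]] <- seq_len(next_label)
    labels[idx] <- remap[labels[idx]]
    info <- do.call(rbind, info)
    info <- info[order(remap[info$label]), , drop = FALSE]
    info$label <- seq_len(next_label)
    rownames(info) <- NULL
  } else {
    info <- data.frame(label = integer(), n_pixels = integer(),
                       bin_lo = numeric(), bin_hi = numeric(),
                       bin_freq = numeric())
  }
  structure(list(labels = labels, n_patches = next_label,
                 bin_width = bin_width, patches = info,
                 pixel_size = freq_map$pixel_size),
            class = "cilia_patches")
}

#' @export
print.cilia_patches <- function(x, ...) {
  cat(sprintf("<cilia_patches> %d patches (bin width %.4g Hz) on %d x %d px\n",
              x$n_patches, x$bin_width, nrow(x$labels), ncol(x$labels)))
  if (x$n_patches > 0) print(utils::head(x$patches, 10))
  invisible(x)
}

#' Dominant frequency of each patch
#'
#' For each patch, the discrete spectral line (of the full-length per-pixel
#' transform) that maximizes the total spectral power summed over the
#' patch's pixels, restricted to the patch's own frequency bin. This is the
#' frequency at which patch phases are subsequently read, so that all
#' phases within a patch are comparable.
#'
#' @param patch_map a [segment_frequency_patches()] result.
#' @param spectra the [pixel_spectra()] of the same recording.
#' @return `patch_map` with a `dominant_freq` column (Hz) added to
#'   `$patches`.
#' @export
patch_dominant_frequency <- function(patch_map, spectra) {
  stopifnot(inherits(patch_map, "cilia_patches"),
            inherits(spectra, "cilia_spectra"))
  d <- dim(spectra$coefficients)
  if (!identical(d[2:3], dim(patch_map$labels)))
    stopf("patch map and spectra geometries differ")
  nf <- d[1]
  coef <- spectra$coefficients
  dim(coef) <- c(nf, d[2] * d[3])
  dom <- numeric(patch_map$n_patches)
  for (p in seq_len(patch_map$n_patches)) {
    pix <- which(patch_map$labels == p)
    row <- patch_map$patches[p, ]
    sel <- which(spectra$freqs >= row$bin_lo & spectra$freqs < row$bin_hi)
    if (length(sel) == 0)  # bin narrower than the line spacing: nearest line
      sel <- which.min(abs(spectra$freqs - row$bin_freq))
    power <- rowSums(abs(coef[sel, pix, drop = FALSE])^2)
    dom[p] <- spectra$freqs[sel[which.max(power)]]
  }
  patch_map$patches$dominant_freq <- dom
  patch_map
}
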