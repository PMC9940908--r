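# End-to-end pipeline: CBF map -> signal mask -> frequency patches ->
# phases -> wave field, with optional coherence stages, writing maps,
# tables and a run manifest.

#' Pipeline configuration
#'
#' All stage parameters in one place, with the standard defaults:
#' downsample 5, detection band `[15, Fs/2]` Hz, 3x3 SD mask at 3 Hz with
#' 500 px minimum region, 100 frequency bins, 200 px minimum patch, Welch
#' 100/80/100, 0.5 um distance and 0.04 coherence histogram bins,
#' coherence thresholds 0.5 / 0.3 / 0.25 and power thresholds 10% / 25%.
#'
#' @param ... overrides for any default listed above (see the source for
#'   names).
#' @return A named list of class `cilia_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    downsample = 5L,
    f_min = 15,
    sd_kernel = 3L, sd_threshold = 3, min_region = 500L,
    n_bins = 100L, connectivity = 8L, min_patch = 200L,
    welch_window = 100L, welch_overlap = 80L, welch_nfft = 100L,
    distance_bin = 0.5, coherence_bin = 0.04,
    coherence_threshold = 0.25,
    mag_bin = 0.01, min_gradient_pixels = 10L,
    wavelength_method = "mean_vector",
    n_pairs = 2e5,
    window_s = NULL, stride_s = 10,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = "cilia_config")
}

analyse_window <- function(rec, cfg) {
  spectra <- pixel_spectra(rec, min_frames = 2L)
  fmap <- peak_frequency_map(spectra, f_min = cfg$f_min)
  mask <- signal_mask(fmap, kernel = cfg$sd_kernel,
                      sd_threshold = cfg$sd_threshold,
                      min_region = cfg$min_region)
  patches <- segment_frequency_patches(fmap, mask, rec$frame_rate,
                                       n_bins = cfg$n_bins,
                                       connectivity = cfg$connectivity,
                                       min_patch = cfg$min_patch)
  patches <- patch_dominant_frequency(patches, spectra)
  phase <- phase_map(spectra, patches)
  waves <- wave_field(phase, patches, mag_bin = cfg$mag_bin,
                      min_pixels = cfg$min_gradient_pixels,
                      method = cfg$wavelength_method)
  list(spectra = spectra, freq_map = fmap, mask = mask, patches = patches,
       phase = phase, waves = waves)
}

#' Run the full analysis pipeline
#'
#' Executes CBF mapping, signal masking, frequency-patch segmentation,
#' phase extraction and wave-field analysis on a recording (optionally in
#' sliding time windows), writes all maps (TIFF + JSON sidecars), the
#' per-patch wave table (CSV) and a manifest echoing every parameter, and
#' returns the results invisibly.
#'
#' @param rec a [recording()] or a path to a multi-page grayscale TIFF.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param config a [pipeline_config()].
#' @param frame_rate,pixel_size acquisition metadata, required when `rec`
#'   is a path.
#' @param reference optional `c(row, col)` (coordinates of the
#'   *downsampled* map) to also run the coherence stage against.
#' @return Invisibly, a list with the per-stage results (`freq_map`,
#'   `mask`, `patches`, `phase`, `waves`, optionally `coherence`,
#'   `classes`); for sliding-window runs, one such list per window in
#'   `$windows`.
#' @export
run_pipeline <- function(rec, out_dir = NULL, config = pipeline_config(),
                         frame_rate = NULL, pixel_size = NULL,
                         reference = NULL) {
  if (is.character(rec)) {
    if (is.null(frame_rate) || is.null(pixel_size))
      stopf("frame_rate and pixel_size are required when loading from a file")
    rec <- load_recording(rec, frame_rate, pixel_size)
  }
  stopifnot(inherits(rec, "cilia_recording"), inherits(config, "cilia_config"))
  small <- downsample_stack(rec, config$downsample)

  if (!is.null(config$window_s)) {
    wlen <- round(config$window_s * small$frame_rate)
    stride <- round(config$stride_s * small$frame_rate)
    starts <- seq(1L, n_frames(small) - wlen + 1L, by = stride)
    windows <- lapply(starts, function(s) {
      sub <- recording(small$stack[s:(s + wlen - 1L), , , drop = FALSE],
                       small$frame_rate, small$pixel_size, small$origin_note)
      analyse_window(sub, config)
    })
    res <- list(windows = windows,
                window_starts_s = (starts - 1) / small$frame_rate)
  } else {
    res <- analyse_window(small, config)
    if (!is.null(reference)) {
      spec <- welch_spec(config$welch_window, config$welch_overlap,
                         config$welch_nfft, small$frame_rate)
      res$coherence <- coherence_map(small, reference, res$mask, spec)
      res$classes <- classify_pixels(res$coherence)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(parameters = unclass(config),
                     frame_rate = rec$frame_rate,
                     pixel_size = rec$pixel_size,
                     frames = n_frames(rec),
                     package_version = as.character(utils::packageVersion("ciliakit")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    if (!is.null(res$waves)) {
      save_map(res$freq_map, file.path(out_dir, "frequency_map.tif"))
      save_map(res$mask, file.path(out_dir, "signal_mask.tif"))
      save_map(res$phase, file.path(out_dir, "phase_map.tif"))
      utils::write.csv(res$waves, file.path(out_dir, "waves.csv"),
                       row.names = FALSE)
      utils::write.csv(res$patches$patches, file.path(out_dir, "patches.csv"),
                       row.names = FALSE)
    } else {
      for (w in seq_along(res$windows))
        utils::write.csv(res$windows[[w]]$waves,
                         file.path(out_dir, sprintf("waves_window%03d.csv", w)),
                         row.names = FALSE)
    }
  }
  invisible(res)
}
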