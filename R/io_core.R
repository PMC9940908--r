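#' Recording objects
#'
#' A `Recording` bundles a grayscale time-lapse stack with its acquisition
#' metadata. The stack is stored as a 3-D double array indexed
#' `[frame, row, col]`, row-major image convention: row 1 is the top image
#' row, rows increase downward, columns increase rightward. All downstream
#' angles are reported in this frame (+x along columns, +y along rows).
#'
#' @param stack numeric array, frames x rows x cols (a matrix is treated as
#'   a single frame).
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param origin_note free-text provenance (organ, side, condition).
#' @return An object of class `cilia_recording` with elements `stack`,
#'   `frame_rate`, `pixel_size`, `origin_note`.
#' @export
recording <- function(stack, frame_rate, pixel_size, origin_note = "") {
  if (length(dim(stack)) == 2L) dim(stack) <- c(1L, dim(stack))
  if (length(dim(stack)) != 3L)
    stopf("stack must be a frames x rows x cols array")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stopf("frame_rate must be a single positive number (Hz)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a single positive number (um/px)")
  if (anyNA(stack) || !all(is.finite(stack)))
    stopf("stack contains non-finite values")
  storage.mode(stack) <- "double"
  structure(
    list(stack = stack, frame_rate = frame_rate, pixel_size = pixel_size,
         origin_note = origin_note),
    class = "cilia_recording")
}

#' @export
print.cilia_recording <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf(
    "<cilia_recording> %d frames of %d x %d px | %.4g Hz | %.4g um/px (%.1f s)\n",
    d[1], d[2], d[3], x$frame_rate, x$pixel_size, d[1] / x$frame_rate))
  if (nzchar(x$origin_note)) cat(" ", x$origin_note, "\n")
  invisible(x)
}

n_frames <- function(rec) dim(rec$stack)[1]

#' Load a multi-page grayscale TIFF recording
#'
#' Reads an uncompressed multi-page grayscale TIFF (8/16-bit unsigned or
#' 32/64-bit float samples) in acquisition order. Integer samples are
#' promoted to double before any spectral analysis to avoid overflow in
#' windowed products. Frame order and pixel axes are preserved exactly:
#' pixel (r, c) of page t in the file becomes `stack[t, r, c]`.
#'
#' @param path path to the TIFF file.
#' @inheritParams recording
#' @param min_frames minimum number of frames required for the default
#'   spectral parameters (two Welch windows); shorter files are rejected.
#' @return A [recording()] object.
#' @export
load_recording <- function(path, frame_rate, pixel_size, origin_note = "",
                           min_frames = 200L) {
  stack <- read_tiff_stack(path)
  if (dim(stack)[1] < min_frames)
    stopf(paste0(
      "recording '%s' has only %d frames; at least %d are required for ",
      "spectral analysis (record longer, or lower min_frames if you will ",
      "use shorter Welch windows)"), path, dim(stack)[1], min_frames)
  rec <- recording(stack, frame_rate, pixel_size, origin_note)
  rec
}

#' Map images
#'
#' A `MapImage` is a 2-D scalar field over (a possibly downsampled copy of)
#' the recording geometry, with a validity mask and physical pixel size.
#' Values are finite exactly where the mask is `TRUE` and `NA` elsewhere.
#'
#' @param values numeric matrix.
#' @param units label: `"Hz"`, `"rad"`, `"dimensionless"`, `"um"`, ...
#' @param mask logical matrix of valid pixels (default: finite values).
#' @param pixel_size um per pixel after any downsampling.
#' @param params named list of the parameters that produced the map
#'   (stored in the JSON sidecar by [save_map()]).
#' @return An object of class `cilia_map`.
#' @export
map_image <- function(values, units, mask = NULL, pixel_size = NA_real_,
                      params = list()) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(values), dim(mask)), is.logical(mask))
  values[!mask] <- NA_real_
  if (any(!is.finite(values[mask])))
    stopf("map values must be finite wherever mask is TRUE")
  structure(list(values = values, units = units, mask = mask,
                 pixel_size = pixel_size, params = params),
            class = "cilia_map")
}

#' @export
print.cilia_map <- function(x, ...) {
  cat(sprintf("<cilia_map> %d x %d px [%s], %d valid px, %.4g um/px\n",
              nrow(x$values), ncol(x$values), x$units, sum(x$mask),
              x$pixel_size))
  invisible(x)
}

#' Save / load a map image
#'
#' `save_map()` writes the map as a 64-bit float single-page TIFF (`NA`
#' outside the mask) plus a JSON sidecar (`<path>.json`) recording units,
#' pixel size and the parameters that produced the map. `load_map()`
#' reverses it; the round trip is exact on the mask.
#'
#' @param map a [map_image()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `save_map()` returns `path` invisibly; `load_map()` a `cilia_map`.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "cilia_map"))
  if (!any(map$mask))
    warning("saving map with empty mask (all values NA)", call. = FALSE)
  write_tiff_stack(map$values, path, type = "float64")
  sidecar <- list(units = map$units, pixel_size = map$pixel_size,
                  params = map$params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  values <- read_tiff_stack(path)[1, , ]
  meta <- list(units = "unknown", pixel_size = NA_real_, params = list())
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar))
  }
  px <- suppressWarnings(as.numeric(meta$pixel_size))
  map_image(values, units = meta$units,
            pixel_size = if (length(px) == 1 && is.finite(px)) px else NA_real_,
            params = meta$params)
}
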