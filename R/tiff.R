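# Minimal baseline-TIFF I/O for multi-page grayscale stacks.
#
# No TIFF package ships with this toolchain, so the subset of the format the
# toolkit needs is implemented here: uncompressed, strip-based, single-channel
# pages; 8/16-bit unsigned integer and 32/64-bit IEEE float samples; either
# byte order on read, little-endian ("II") on write. This is deliberately not
# a general TIFF library.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L
)

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

read_raw_int <- function(raw, offset, size, n, endian, signed = FALSE) {
  bytes <- raw[(offset + 1):(offset + size * n)]
  # readBin only honours signed = FALSE for 1- and 2-byte integers; 4-byte
  # values are read signed here and wrapped to unsigned by the callers
  readBin(bytes, "integer", n = n, size = size,
          signed = if (size > 2L) TRUE else signed, endian = endian)
}

# Parse one IFD; returns list(tags = named list of numeric vectors,
# next_offset).
read_ifd <- function(raw, offset, endian) {
  n_entries <- read_raw_int(raw, offset, 2L, 1L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- offset + 2L + (i - 1L) * 12L
    tag   <- read_raw_int(raw, e, 2L, 1L, endian)
    type  <- read_raw_int(raw, e + 2L, 2L, 1L, endian)
    count <- read_raw_int(raw, e + 4L, 4L, 1L, endian)
    tsize <- tiff_type_size[as.character(type)]
    if (is.na(tsize)) next  # RATIONAL etc. — not needed for our tags
    nbytes <- tsize * count
    voff <- if (nbytes > 4L) read_raw_int(raw, e + 8L, 4L, 1L, endian) else e + 8L
    vals <- switch(as.character(type),
      `1` = read_raw_int(raw, voff, 1L, count, endian),
      `2` = read_raw_int(raw, voff, 1L, count, endian),
      `3` = read_raw_int(raw, voff, 2L, count, endian),
      `4` = {
        v <- as.numeric(read_raw_int(raw, voff, 4L, count, endian))
        v[v < 0] <- v[v < 0] + 2^32
        v
      })
    tags[[as.character(tag)]] <- vals
  }
  next_ifd <- offset + 2L + n_entries * 12L
  nxt <- as.numeric(read_raw_int(raw, next_ifd, 4L, 1L, endian))
  if (nxt < 0) nxt <- nxt + 2^32
  list(tags = tags, next_offset = nxt)
}

tag_val <- function(ifd, name, default = NULL) {
  v <- ifd$tags[[as.character(TIFF_TAGS[[name]])]]
  if (is.null(v)) default else v
}

# Read a multi-page grayscale TIFF into an array (frames x rows x cols),
# always promoted to double.
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stopf("cannot read TIFF: '%s' does not exist", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("'%s' is not a TIFF file (truncated header)", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("'%s' is not a TIFF file (bad byte-order mark)", path))
  if (read_raw_int(raw, 2L, 2L, 1L, endian) != 42L)
    stopf("'%s' is not a TIFF file (bad magic number)", path)
  offset <- as.numeric(read_raw_int(raw, 4L, 4L, 1L, endian))
  if (offset < 0) offset <- offset + 2^32

  frames <- list()
  while (offset != 0) {
    ifd <- read_ifd(raw, offset, endian)
    frames[[length(frames) + 1L]] <- decode_page(raw, ifd, endian, path)
    offset <- ifd$next_offset
  }
  if (length(frames) == 0) stopf("'%s' contains no images", path)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("'%s': pages have inconsistent dimensions", path)
  stack <- array(NA_real_, dim = c(length(frames), dims[1, 1], dims[2, 1]))
  for (t in seq_along(frames)) stack[t, , ] <- frames[[t]]
  stack
}

decode_page <- function(raw, ifd, endian, path) {
  spp <- tag_val(ifd, "samples_per_pixel", 1L)
  photometric <- tag_val(ifd, "photometric", 1L)
  if (spp != 1L || photometric > 1L)
    stopf("'%s': single-channel (grayscale) TIFF required", path)
  if (tag_val(ifd, "compression", 1L) != 1L)
    stopf("'%s': only uncompressed TIFF is supported", path)
  w <- tag_val(ifd, "width"); h <- tag_val(ifd, "length")
  bits <- tag_val(ifd, "bits", 1L)
  fmt <- tag_val(ifd, "sample_format", 1L)
  if (is.null(w) || is.null(h)) stopf("'%s': page missing dimensions", path)
  offs <- tag_val(ifd, "strip_offsets")
  cnts <- tag_val(ifd, "strip_counts")
  if (is.null(offs) || is.null(cnts)) stopf("'%s': page missing strip data", path)
  bytes <- unlist(lapply(seq_along(offs), function(i) {
    raw[(offs[i] + 1):(offs[i] + cnts[i])]
  }), use.names = FALSE)
  n <- w * h
  vals <- if (fmt == 3L) {
    if (!bits %in% c(32L, 64L))
      stopf("'%s': unsupported float bit depth %d", path, bits)
    readBin(bytes, "double", n = n, size = bits / 8L, endian = endian)
  } else if (fmt %in% c(1L, 2L)) {
    if (!bits %in% c(8L, 16L, 32L))
      stopf("'%s': unsupported integer bit depth %d", path, bits)
    signed <- fmt == 2L
    v <- as.numeric(readBin(bytes, "integer", n = n, size = bits / 8L,
                            signed = if (bits == 32L) TRUE else signed,
                            endian = endian))
    if (!signed && bits == 32L) v[v < 0] <- v[v < 0] + 2^32
    v
  } else stopf("'%s': unsupported sample format %d", path, fmt)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# Write an array (frames x rows x cols) as a little-endian multi-page
# grayscale TIFF. `type` controls the sample encoding; float64 round-trips
# doubles exactly.
write_tiff_stack <- function(stack, path,
                             type = c("float64", "float32", "uint16", "uint8")) {
  type <- match.arg(type)
  if (length(dim(stack)) == 2L) dim(stack) <- c(1L, dim(stack))
  stopifnot(length(dim(stack)) == 3L)
  nt <- dim(stack)[1]; nr <- dim(stack)[2]; nc <- dim(stack)[3]
  bits <- switch(type, float64 = 64L, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (startsWith(type, "float")) 3L else 1L
  page_bytes <- nr * nc * bits / 8L
  pad <- page_bytes %% 2L
  data_start <- 8L
  ifd_start <- data_start + nt * (page_bytes + pad)
  ifd_size <- 2L + 10L * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (t in seq_len(nt)) {
    vals <- as.vector(t(stack[t, , , drop = TRUE]))
    if (fmt == 3L) {
      writeBin(as.numeric(vals), con, size = bits / 8L, endian = "little")
    } else {
      writeBin(as.integer(round(vals)), con, size = bits / 8L,
               endian = "little", useBytes = TRUE)
    }
    if (pad) writeBin(as.raw(0L), con)
  }
  entry <- function(tag, type_id, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type_id), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type_id == 3L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (t in seq_len(nt)) {
    strip_offset <- data_start + (t - 1L) * (page_bytes + pad)
    writeBin(10L, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, nc)               # ImageWidth
    entry(257L, 4L, 1L, nr)               # ImageLength
    entry(258L, 3L, 1L, bits)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)               # Compression: none
    entry(262L, 3L, 1L, 1L)               # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_offset)     # StripOffsets
    entry(277L, 3L, 1L, 1L)               # SamplesPerPixel
    entry(278L, 4L, 1L, nr)               # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)       # StripByteCounts
    entry(339L, 3L, 1L, fmt)              # SampleFormat
    next_off <- if (t < nt) ifd_start + t * ifd_size else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}
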