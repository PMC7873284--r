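# Minimal baseline TIFF support for grayscale volume stacks.
#
# No TIFF package is available in the deployment image, so the subset of
# baseline TIFF needed for single-channel volumes is implemented here:
# uncompressed, strip-based, little- or big-endian, 8/16-bit unsigned
# integer or 32-bit float samples, one image per page. This is a format
# shim, not a general TIFF library.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_tiff_value <- function(con, type, count, endian) {
  size <- TIFF_TYPE_SIZES[type]
  switch(as.character(type),
         "3" = readBin(con, "integer", n = count, size = 2L, signed = FALSE,
                       endian = endian),
         "4" = readBin(con, "integer", n = count, size = 4L, endian = endian),
         "1" = readBin(con, "integer", n = count, size = 1L, signed = FALSE),
         readBin(con, "raw", n = count * size))
}

read_ifd_entries <- function(con, endian) {
  n <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  entries <- list()
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", size = 4L, endian = endian)
    size <- if (type >= 1L && type <= 12L) TIFF_TYPE_SIZES[type] else 1L
    here <- seek(con)
    if (size * count <= 4L) {
      val <- read_tiff_value(con, type, count, endian)
      seek(con, here + 4L)
    } else {
      off <- readBin(con, "integer", size = 4L, endian = endian)
      seek(con, off)
      val <- read_tiff_value(con, type, count, endian)
      seek(con, here + 4L)
    }
    entries[[as.character(tag)]] <- val
  }
  next_ifd <- readBin(con, "integer", size = 4L, endian = endian)
  list(entries = entries, next_ifd = next_ifd)
}

#' Read a multi-page grayscale TIFF volume
#'
#' Reads an uncompressed single-channel baseline TIFF stack into a 3D
#' array with axes (x, y, z), z being the page index; integer sample
#' types are converted to double.
#'
#' @param path Path to the TIFF file.
#' @return 3D numeric array of dimensions width x height x pages.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
            else if (identical(as.integer(magic), c(0x4dL, 0x4dL))) "big"
            else stop_srp("not a TIFF file (bad byte-order mark)")
  forty2 <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  if (forty2 != 42L) stop_srp("not a TIFF file (bad magic number)")
  offset <- readBin(con, "integer", size = 4L, endian = endian)
  slices <- list()
  while (offset != 0L) {
    seek(con, offset)
    ifd <- read_ifd_entries(con, endian)
    e <- ifd$entries
    need <- function(tag, default = NULL) {
      v <- e[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_srp(sprintf("TIFF tag %d missing", tag))
        default
      } else v
    }
    width <- need(256L)
    height <- need(257L)
    bits <- need(258L, 1L)
    compression <- need(259L, 1L)
    spp <- need(277L, 1L)
    fmt <- need(339L, 1L)
    if (compression != 1L) stop_srp("unsupported TIFF: compressed data")
    if (length(bits) > 1L || spp != 1L) {
      stop_srp("unsupported TIFF: not single-channel grayscale")
    }
    photometric <- need(262L, 1L)
    if (!photometric %in% c(0L, 1L)) {
      stop_srp("unsupported TIFF: not single-channel grayscale")
    }
    offsets <- need(273L)
    counts <- need(279L)
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      npx <- counts[s] / (bits / 8L)
      v <- if (fmt == 3L) {
        if (bits != 32L) stop_srp("unsupported TIFF: float samples must be 32-bit")
        readBin(con, "double", n = npx, size = 4L, endian = endian)
      } else if (bits == 8L) {
        readBin(con, "integer", n = npx, size = 1L, signed = FALSE)
      } else if (bits == 16L) {
        readBin(con, "integer", n = npx, size = 2L, signed = FALSE, endian = endian)
      } else {
        stop_srp(sprintf("unsupported TIFF: %d-bit integer samples", bits))
      }
      vals <- c(vals, as.numeric(v))
    }
    if (length(vals) != width * height) stop_srp("corrupt TIFF: truncated strip data")
    slices[[length(slices) + 1L]] <- matrix(vals, nrow = width, ncol = height)
    offset <- ifd$next_ifd
  }
  if (length(slices) == 0L) stop_srp("TIFF file contains no pages")
  array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
}

#' Write a volume as a multi-page grayscale TIFF
#'
#' Writes an uncompressed little-endian baseline TIFF, one page per slice,
#' one strip per page; `type = "uint16"` (default) rounds and clamps to
#' 0..65535, `type = "float32"` stores 32-bit floats.
#'
#' @param volume 3D numeric array (x, y, z) or a matrix (written as one page).
#' @param path Output path.
#' @param type `"uint16"` or `"float32"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, type = c("uint16", "float32")) {
  type <- match.arg(type)
  if (is.matrix(volume)) volume <- array(volume, dim = c(dim(volume), 1L))
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    stop_srp("volume must be a 3D array or a matrix")
  }
  d <- dim(volume)
  bps <- if (type == "uint16") 2L else 4L
  page_bytes <- d[1L] * d[2L] * bps
  n_entries <- 9L
  ifd_bytes <- 2L + 12L * n_entries + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)
  first_ifd <- 8L + d[3L] * page_bytes
  writeBin(first_ifd, con, size = 4L, endian = "little")
  for (z in seq_len(d[3L])) {
    v <- as.vector(volume[, , z])
    if (type == "uint16") {
      v <- pmin(pmax(round(v), 0), 65535)
      # writeBin has no unsigned 16-bit mode; map to signed range.
      v <- as.integer(ifelse(v > 32767, v - 65536, v))
      writeBin(v, con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
  }
  entry <- function(tag, type_id, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type_id), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  for (z in seq_len(d[3L])) {
    writeBin(n_entries, con, size = 2L, endian = "little")
    entry(256L, 4L, 1L, d[1L])                    # ImageWidth
    entry(257L, 4L, 1L, d[2L])                    # ImageLength
    entry(258L, 3L, 1L, 8L * bps)                 # BitsPerSample
    entry(259L, 3L, 1L, 1L)                       # Compression: none
    entry(262L, 3L, 1L, 1L)                       # Photometric: BlackIsZero
    entry(273L, 4L, 1L, 8L + (z - 1L) * page_bytes) # StripOffsets
    entry(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    entry(279L, 4L, 1L, page_bytes)               # StripByteCounts
    entry(339L, 3L, 1L, if (type == "uint16") 1L else 3L) # SampleFormat
    next_off <- if (z == d[3L]) 0L else first_ifd + z * ifd_bytes
    writeBin(next_off, con, size = 4L, endian = "little")
  }
  invisible(path)
}
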