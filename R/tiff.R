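# Minimal baseline TIFF I/O for 16-bit grayscale field images.
#
# The package deliberately carries its own reader/writer for the one TIFF
# flavour the pipeline produces and consumes (uncompressed, single-sample,
# 8- or 16-bit grayscale, strip-organised): no TIFF package is available in
# the supported R installation. The writer emits little-endian baseline
# files that standard tools (tifffile, ImageJ) open unchanged; the reader
# accepts both byte orders and multi-strip layouts but nothing fancier.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L) # BYTE, ASCII, SHORT, LONG, RATIONAL

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Pixel values are clamped to the unsigned 16-bit range and rounded.
#' The matrix is interpreted with rows as image rows (row `1` is the top
#' scanline).
#'
#' @param image Numeric matrix of pixel intensities.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tif")
#' write_tiff16(matrix(0:3, 2, 2), f)
#' read_tiff16(f)
write_tiff16 <- function(image, path) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_hcs("hcs_input_error", "`image` must be a numeric matrix")
  }
  px <- as.integer(pmin(pmax(round(t(image)), 0), 65535)) # row-major order
  h <- nrow(image)
  w <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  n_bytes <- length(px) * 2L
  ifd_offset <- data_offset + n_bytes
  # header
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data as unsigned 16-bit little-endian (manual byte packing: R's
  # writeBin cannot represent values > 32767 at size 2)
  writeBin(as.raw(rbind(px %% 256L, px %/% 256L)), con)
  # IFD: tag, type, count, value
  entries <- list(
    c(256L, 4L, 1L, w),           # ImageWidth
    c(257L, 4L, 1L, h),           # ImageLength
    c(258L, 3L, 1L, 16L),         # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression = none
    c(262L, 3L, 1L, 1L),          # Photometric = BlackIsZero
    c(273L, 4L, 1L, data_offset), # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 4L, 1L, h),           # RowsPerStrip
    c(279L, 4L, 1L, n_bytes)      # StripByteCounts
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) { # SHORT values are left-justified in the 4-byte slot
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff16()]
#'
#' Supports uncompressed single-sample 8- or 16-bit grayscale baseline TIFF
#' in either byte order, with one or more strips.
#'
#' @param path File path.
#' @return Integer matrix of pixel intensities (rows = image rows).
#' @export
read_tiff16 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop_hcs("hcs_input_error", "not a TIFF file: %s", path)
  magic <- rawToChar(raw_all[1:2])
  endian <- switch(magic, II = "little", MM = "big",
    stop_hcs("hcs_input_error", "not a TIFF file: %s", path)
  )
  rd_int <- function(offset, size, n = 1) {
    readBin(raw_all[(offset + 1):(offset + size * n)], "integer",
      n = n, size = size, signed = size >= 4, endian = endian
    )
  }
  if (rd_int(2, 2) != 42L) stop_hcs("hcs_input_error", "bad TIFF magic in %s", path)
  ifd <- rd_int(4, 4)
  n_entries <- rd_int(ifd, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- rd_int(base, 2)
    type <- rd_int(base + 2, 2)
    count <- rd_int(base + 4, 4)
    size <- TIFF_TYPE_SIZES[min(type, 5L)]
    values <- if (size * count <= 4) {
      rd_int(base + 8, size, count)
    } else {
      rd_int(rd_int(base + 8, 4), size, count)
    }
    tags[[as.character(tag)]] <- values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_hcs("hcs_input_error", "TIFF tag %d missing in %s", tag, path)
      default
    } else v
  }
  w <- need(256)
  h <- need(257)
  bits <- need(258, 1L)
  if (need(259, 1L) != 1L) stop_hcs("hcs_input_error", "compressed TIFF not supported: %s", path)
  if (need(277, 1L) != 1L || !(bits %in% c(8L, 16L))) {
    stop_hcs("hcs_input_error", "only single-sample 8/16-bit grayscale supported: %s", path)
  }
  strip_offsets <- need(273)
  strip_bytes <- need(279, w * h * bits / 8)
  px <- integer(0)
  for (s in seq_along(strip_offsets)) {
    n_px <- strip_bytes[s] / (bits / 8)
    vals <- readBin(
      raw_all[(strip_offsets[s] + 1):(strip_offsets[s] + strip_bytes[s])],
      "integer", n = n_px, size = bits / 8, signed = FALSE, endian = endian
    )
    px <- c(px, vals)
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
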