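# Minimal uncompressed 8-bit RGB TIFF I/O (little-endian, single plane).
# No image-format package is part of this package's dependency contract, so
# the small baseline-TIFF subset needed for section images is implemented
# here directly; the writer is cross-checked against an independent reader
# in the test suite.

.tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

#' Write an 8-bit RGB image as an uncompressed baseline TIFF
#'
#' @param pixels Integer array `height x width x 3` with values in 0..255.
#' @param path Output file path.
#' @export
write_rgb_tiff <- function(pixels, path) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must be in 0..255", call. = FALSE)
  h <- d[1L]; w <- d[2L]
  con <- file(path, "wb"); on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == .tiff_types[["SHORT"]] && count == 1L) { w16(value); w16(0L) }
    else w32(value)
  }
  n_tags <- 10L
  ifd_off <- 8L
  bps_off <- ifd_off + 2L + n_tags * 12L + 4L   # BitsPerSample triple
  data_off <- bps_off + 6L
  writeChar("II", con, nchars = 2L, eos = NULL); w16(42L); w32(ifd_off)
  w16(n_tags)
  entry(256L, 4L, 1L, w)                 # ImageWidth
  entry(257L, 4L, 1L, h)                 # ImageLength
  entry(258L, 3L, 3L, bps_off)           # BitsPerSample = 8,8,8
  entry(259L, 3L, 1L, 1L)                # Compression = none
  entry(262L, 3L, 1L, 2L)                # Photometric = RGB
  entry(273L, 4L, 1L, data_off)          # StripOffsets
  entry(277L, 3L, 1L, 3L)                # SamplesPerPixel
  entry(278L, 4L, 1L, h)                 # RowsPerStrip
  entry(279L, 4L, 1L, w * h * 3L)        # StripByteCounts
  entry(284L, 3L, 1L, 1L)                # PlanarConfiguration = chunky
  w32(0L)                                # no next IFD
  w16(c(8L, 8L, 8L))
  # interleaved RGBRGB..., row-major from the top-left pixel
  writeBin(as.raw(as.integer(aperm(pixels, c(3L, 2L, 1L)))), con)
  invisible(path)
}

#' Read an uncompressed 8-bit RGB TIFF
#'
#' Supports the baseline subset emitted by [write_rgb_tiff()] (both byte
#' orders, chunky planar configuration, any strip layout).
#'
#' @param path TIFF file path.
#' @return Integer array `height x width x 3`.
#' @export
read_rgb_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  rd <- function(off, size, n = 1L)   # size-4 reads are signed; offsets < 2^31
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L, endian = endian)
  if (rd(2L, 2L) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- rd(4L, 4L)
  n_tags <- rd(ifd, 2L)
  tags <- list()
  for (k in seq_len(n_tags)) {
    e <- ifd + 2L + (k - 1L) * 12L
    tag <- rd(e, 2L); type <- rd(e + 2L, 2L); count <- rd(e + 4L, 4L)
    size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
    vals <- if (size * count <= 4L) rd(e + 8L, size, count)
            else rd(rd(e + 8L, 4L), size, count)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF tag ", tag, " missing in ", path, call. = FALSE)
    v
  }
  w <- need(256L); h <- need(257L)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("compressed TIFF not supported: ", path, call. = FALSE)
  if (need(277L) != 3L || !all(need(258L) == 8L))
    stop("only 8-bit RGB TIFF supported: ", path, call. = FALSE)
  if (!is.null(tags[["284"]]) && tags[["284"]] != 1L)
    stop("planar TIFF not supported: ", path, call. = FALSE)
  offs <- need(273L); counts <- need(279L)
  bytes <- unlist(lapply(seq_along(offs), function(i)
    as.integer(raw[(offs[i] + 1L):(offs[i] + counts[i])])), use.names = FALSE)
  if (length(bytes) != w * h * 3L)
    stop("TIFF pixel data truncated: ", path, call. = FALSE)
  aperm(array(bytes, dim = c(3L, w, h)), c(3L, 2L, 1L))
}
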