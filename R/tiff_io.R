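# Minimal baseline TIFF I/O for grayscale image stacks.
#
# No TIFF package ships with the supported R stack, so the package carries a
# small reader/writer for the baseline subset it needs: uncompressed
# grayscale, 8- or 16-bit unsigned, one or more strips per page, one page
# per z-slice.  Files written here are readable by ImageJ / tifffile; the
# reader handles both byte orders.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write a 3D stack as a multi-page grayscale TIFF
#'
#' One page per z-slice, uncompressed, little-endian, 16-bit (or 8-bit)
#' unsigned grayscale.
#'
#' @param stack numeric 3D array (z, y, x) of nonnegative integers.
#' @param path output file.
#' @param bits 16 (default) or 8.
#' @return the path, invisibly.
#' @export
write_tiff_stack <- function(stack, path, bits = 16L) {
  stopifnot(length(dim(stack)) == 3, bits %in% c(8L, 16L))
  maxval <- if (bits == 16L) 65535 else 255
  if (any(stack < 0) || any(stack > maxval))
    abort_np(sprintf("intensities must lie in [0, %d]", maxval),
             "np_param_error")
  nz <- dim(stack)[1]; ny <- dim(stack)[2]; nx <- dim(stack)[3]
  bpp <- bits %/% 8L
  page_bytes <- nx * ny * bpp
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout: header | page1 data | IFD1 | page2 data | IFD2 | ...
  first_data <- 8L
  writeBin(as.integer(first_data + page_bytes), con, size = 4,
           endian = "little")   # offset of first IFD
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  offset <- first_data
  for (z in seq_len(nz)) {
    # row-major pixel order: x fastest within a row, rows top to bottom
    slice <- t(matrix(stack[z, , ], ny, nx))   # nx x ny; column = one row
    writeBin(as.integer(as.vector(slice)), con, size = bpp,
             endian = "little")
    data_off <- offset
    ifd_off <- offset + page_bytes
    next_ifd <- if (z < nz) ifd_off + ifd_bytes + page_bytes else 0L
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(TIFF_TAGS["width"], 4L, 1L, nx)
    entry(TIFF_TAGS["length"], 4L, 1L, ny)
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)  # BlackIsZero
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
    entry(TIFF_TAGS["samples_per_pixel"], 3L, 1L, 1L)
    entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, ny)
    entry(TIFF_TAGS["strip_byte_counts"], 4L, 1L, page_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, 1L)  # unsigned integer
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

# read one IFD; returns list(tags = named list, next_offset)
read_ifd <- function(raw, offset, endian) {
  u16 <- function(at) readBin(raw[at + 1:2], "integer", size = 2,
                              endian = endian, signed = FALSE)
  u32 <- function(at) readBin(raw[at + 1:4], "integer", size = 4,
                              endian = endian)
  n <- u16(offset)
  tags <- list()
  for (i in seq_len(n)) {
    at <- offset + 2L + (i - 1L) * 12L
    tag <- u16(at); type <- u16(at + 2L); count <- u32(at + 4L)
    type_size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
    if (is.na(type_size)) { next }  # skip rationals etc.
    nbytes <- type_size * count
    vals_at <- if (nbytes <= 4L) at + 8L else u32(at + 8L)
    vals <- vapply(seq_len(count), function(j) {
      p <- vals_at + (j - 1L) * type_size
      if (type_size == 2L) u16(p)
      else if (type_size == 4L) u32(p)
      else as.integer(raw[p + 1L])
    }, integer(1))
    tags[[as.character(tag)]] <- vals
  }
  list(tags = tags, next_offset = u32(offset + 2L + n * 12L))
}

#' Read a multi-page grayscale TIFF as a 3D stack
#'
#' Supports the baseline subset written by [write_tiff_stack()] (plus files
#' from ImageJ / tifffile of the same kind): uncompressed grayscale, 8- or
#' 16-bit unsigned, either byte order, any strip layout.
#'
#' @param path TIFF file.
#' @return numeric 3D array (z, y, x).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   abort_np("not a TIFF file", "np_io_error"))
  u32 <- function(at) readBin(raw[at + 1:4], "integer", size = 4,
                              endian = endian)
  magic <- readBin(raw[3:4], "integer", size = 2, endian = endian)
  if (magic != 42L) abort_np("not a TIFF file", "np_io_error")
  offset <- u32(4L)
  slices <- list()
  while (offset != 0L) {
    ifd <- read_ifd(raw, offset, endian)
    tg <- ifd$tags
    g <- function(name, default = NULL) {
      v <- tg[[as.character(TIFF_TAGS[[name]])]]
      if (is.null(v)) default else v
    }
    nx <- g("width"); ny <- g("length")
    bits <- g("bits", 1L)[1]
    if (is.null(nx) || is.null(ny))
      abort_np("TIFF page missing dimensions", "np_io_error")
    if (g("compression", 1L)[1] != 1L)
      abort_np("only uncompressed TIFF is supported", "np_io_error")
    if (g("samples_per_pixel", 1L)[1] != 1L)
      abort_np("only single-sample (grayscale) TIFF is supported",
               "np_io_error")
    if (!bits %in% c(8L, 16L))
      abort_np("only 8- or 16-bit TIFF is supported", "np_io_error")
    bpp <- bits %/% 8L
    offs <- g("strip_offsets"); cnts <- g("strip_byte_counts")
    pix <- unlist(lapply(seq_along(offs), function(s) {
      readBin(raw[offs[s] + seq_len(cnts[s])], "integer", n = cnts[s] %/% bpp,
              size = bpp, endian = endian, signed = FALSE)
    }))
    if (length(pix) != nx * ny)
      abort_np("TIFF strip data does not match page dimensions",
               "np_io_error")
    slices[[length(slices) + 1]] <- matrix(pix, ny, nx, byrow = TRUE)
    offset <- ifd$next_offset
  }
  nz <- length(slices)
  out <- array(0, c(nz, nrow(slices[[1]]), ncol(slices[[1]])))
  for (z in seq_len(nz)) out[z, , ] <- slices[[z]]
  out
}
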