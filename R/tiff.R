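# Minimal baseline TIFF support: multi-page, grayscale, uncompressed,
# little-endian, 8- or 16-bit unsigned. Enough to round-trip the package's
# own movies and to interoperate with standard readers; no external TIFF
# library is required.

.tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

#' Write an image stack as a multi-page TIFF
#'
#' Baseline uncompressed little-endian grayscale TIFF, one page per frame.
#' EMCCD stacks are written as 16-bit unsigned, SPAD (binary) stacks as
#' 8-bit. Pixel `(i, j)` of the package's convention (i = x/column,
#' j = y/row) maps to TIFF column i, row j.
#'
#' @param stack An [image_stack()], or a bare `I x J x N` array.
#' @param path Output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, bits = 16L) {
  values <- if (inherits(stack, "image_stack")) stack$values else stack
  .assert(bits %in% c(8L, 16L), "bits must be 8 or 16")
  .assert(all(values >= 0) && all(values <= 2^bits - 1),
          sprintf("values out of range for %d-bit TIFF", bits))
  .assert(all(values == round(values)), "TIFF values must be integers")
  d <- dim(values)
  nx <- d[1L]; ny <- d[2L]; nf <- d[3L]
  bytes_px <- bits %/% 8L
  strip_bytes <- nx * ny * bytes_px

  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con)
  wr2(42L)
  n_tags <- 10L
  ifd_bytes <- 2L + 12L * n_tags + 4L
  # layout per page: [strip data][IFD]; first IFD offset points past header+page0 data
  page_bytes <- strip_bytes + ifd_bytes
  first_ifd <- 8L + strip_bytes
  wr4(first_ifd)

  tag <- function(code, type, count, value) {
    wr2(code); wr2(type); wr4(count)
    if (type == .tiff_types[["SHORT"]]) {
      wr2(value); wr2(0L)
    } else {
      wr4(value)
    }
  }

  for (n in seq_len(nf)) {
    # frame data: values[, , n] in column-major order is exactly
    # row-major raster order (x fastest) expected by TIFF
    v <- as.integer(values[, , n])
    writeBin(v, con, size = bytes_px, endian = "little")
    data_off <- 8L + (n - 1L) * page_bytes
    wr2(n_tags)
    tag(256L, 3L, 1L, nx)            # ImageWidth
    tag(257L, 3L, 1L, ny)            # ImageLength
    tag(258L, 3L, 1L, bits)          # BitsPerSample
    tag(259L, 3L, 1L, 1L)            # Compression: none
    tag(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off)      # StripOffsets
    tag(277L, 3L, 1L, 1L)            # SamplesPerPixel
    tag(278L, 3L, 1L, ny)            # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)   # StripByteCounts
    tag(339L, 3L, 1L, 1L)            # SampleFormat: unsigned
    wr4(if (n < nf) 8L + n * page_bytes + strip_bytes else 0L)
  }
  invisible(path)
}

# Read one little-endian unsigned integer from a raw vector (1-based offset).
.rd_uint <- function(raw, off, size) {
  v <- as.integer(raw[off:(off + size - 1L)])
  sum(v * 256^(seq_len(size) - 1L))
}

#' Read a multi-page TIFF into an array
#'
#' Supports grayscale, uncompressed, little-endian TIFFs with 8- or 16-bit
#' unsigned samples (possibly split into multiple strips), as written by
#' [write_tiff_stack()] or standard tools.
#'
#' @param path TIFF file path.
#' @return `I x J x N` numeric array (`values[i, j, n]`, i = x/column).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  .assert(rawToChar(raw[1:2]) == "II",
          "only little-endian TIFF is supported")
  .assert(.rd_uint(raw, 3L, 2L) == 42L, "not a TIFF file")
  ifd_off <- .rd_uint(raw, 5L, 4L)
  frames <- list()
  while (ifd_off != 0L) {
    n_tags <- .rd_uint(raw, ifd_off + 1L, 2L)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd_off + 2L + (t - 1L) * 12L + 1L
      code <- .rd_uint(raw, base, 2L)
      type <- .rd_uint(raw, base + 2L, 2L)
      count <- .rd_uint(raw, base + 4L, 4L)
      tsize <- c(1L, 1L, 2L, 4L)[type] # BYTE/ASCII/SHORT/LONG
      if (is.na(tsize) || length(tsize) == 0L) next # ignore exotic tag types
      total <- tsize * count
      voff <- if (total <= 4L) base + 8L else .rd_uint(raw, base + 8L, 4L) + 1L
      vals <- vapply(seq_len(count), function(i)
        .rd_uint(raw, voff + (i - 1L) * tsize, tsize), numeric(1L))
      tags[[as.character(code)]] <- vals
    }
    g <- function(code, default = NULL) tags[[as.character(code)]] %||% default
    width <- g(256L); height <- g(257L)
    bits <- g(258L, 1L)
    .assert(g(259L, 1L) == 1L, "compressed TIFF is not supported")
    .assert(bits %in% c(8L, 16L), "only 8/16-bit TIFF is supported")
    .assert(g(339L, 1L) == 1L, "only unsigned TIFF samples are supported")
    offsets <- g(273L)
    counts <- g(279L, width * height * bits / 8L)
    data <- unlist(lapply(seq_along(offsets), function(s) {
      sl <- raw[(offsets[s] + 1L):(offsets[s] + counts[s])]
      readBin(sl, "integer", n = counts[s] / (bits / 8L), size = bits / 8L,
              signed = FALSE, endian = "little")
    }))
    frames[[length(frames) + 1L]] <- matrix(data, nrow = width, ncol = height)
    ifd_off <- .rd_uint(raw, ifd_off + 2L + n_tags * 12L + 1L, 4L)
  }
  .assert(length(frames) > 0L, "TIFF contains no pages")
  array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
}
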