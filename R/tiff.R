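## Minimal baseline TIFF codec (little-endian, uncompressed, grayscale).
## Implemented here because no TIFF package ships with the analysis stack;
## supports exactly what the renderer and detectors need: multi-page
## single-channel images, 8/16-bit unsigned or 32-bit float samples.

.TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                RowsPerStrip = 278L, StripByteCounts = 279L,
                SampleFormat = 339L)

#' Write a grayscale multi-page TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page.
#'
#' @param stack numeric matrix (one page) or h x w x n array.
#' @param path output file.
#' @param bits 8 or 16 (unsigned integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path, bits = 32L) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L) stopf("'stack' must be a matrix or 3D array")
  if (!bits %in% c(8L, 16L, 32L)) stopf("unsupported bit depth %d", bits)
  h <- dim(stack)[1]; w <- dim(stack)[2]; np <- dim(stack)[3]
  fmt <- if (bits == 32L) 3L else 1L          # SampleFormat: float vs uint
  bytes_px <- bits %/% 8L
  strip_len <- h * w * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  ## layout per page: [pixel strip][IFD]; header points at first IFD
  ifd_size <- 2L + 9L * 12L + 4L
  offs <- 8L
  first_ifd <- offs + strip_len
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (p in seq_len(np)) {
    page <- t(stack[, , p])                   # row-major pixel order
    if (bits == 32L) {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(pmin(pmax(page, 0), 2^bits - 1)))
      writeBin(v, con, size = bytes_px, endian = "little")
    }
    strip_off <- offs
    ifd_off <- strip_off + strip_len
    next_off <- if (p < np) ifd_off + ifd_size + strip_len else 0L
    writeBin(9L, con, size = 2, endian = "little")
    wr_tag <- function(tag, type, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(1L, con, size = 4, endian = "little")
      if (type == 3L) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    wr_tag(256L, 4L, w); wr_tag(257L, 4L, h)
    wr_tag(258L, 3L, bits); wr_tag(259L, 3L, 1L); wr_tag(262L, 3L, 1L)
    wr_tag(273L, 4L, strip_off); wr_tag(278L, 4L, h)
    wr_tag(279L, 4L, strip_len); wr_tag(339L, 3L, fmt)
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    offs <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed little- or big-endian baseline TIFF with 8/16-bit
#' unsigned or 32-bit float samples, one sample per pixel.
#'
#' @param path TIFF file.
#' @return an h x w x n_pages numeric array.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[off + 1:4], "integer", size = 4, endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2) != 42L) stopf("'%s' is not a TIFF file", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n_ent <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2); cnt <- u32(base + 4)
      val <- if (type == 3L && cnt == 1L) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val,
                                        base = base)
    }
    gt <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    w <- gt(256); h <- gt(257)
    bits <- gt(258, 1L); comp <- gt(259, 1L); fmt <- gt(339, 1L)
    if (comp != 1L) stopf("compressed TIFF not supported")
    if (!bits %in% c(8L, 16L, 32L)) stopf("unsupported bit depth %d", bits)
    read_vals <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (t$count == 1L) return(t$value)
      sz <- if (t$type == 3L) 2L else 4L
      off <- t$value
      vapply(seq_len(t$count), function(i) {
        if (sz == 2L) u16(off + (i - 1) * 2) else u32(off + (i - 1) * 4)
      }, numeric(1))
    }
    s_off <- read_vals(273); s_cnt <- read_vals(279)
    buf <- unlist(lapply(seq_along(s_off), function(i)
      raw[s_off[i] + seq_len(s_cnt[i])]), use.names = FALSE)
    n_px <- h * w
    vals <- if (bits == 32L && fmt == 3L) {
      readBin(buf, "numeric", n = n_px, size = 4, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = n_px, size = 1, signed = FALSE,
                         endian = endian))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = n_px, size = 2, signed = FALSE,
                         endian = endian))
    } else stopf("unsupported sample format %d at %d bits", fmt, bits)
    pages[[length(pages) + 1L]] <- t(matrix(vals, w, h))
    ifd <- u32(ifd + 2 + n_ent * 12)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  array(unlist(pages, use.names = FALSE), c(h, w, length(pages)))
}
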