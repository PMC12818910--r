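# Minimal baseline TIFF codec for single-channel image stacks.
#
# Only what time-lapse grayscale microscopy export needs: multi-page,
# uncompressed, single sample per pixel, 8/16-bit unsigned integer or
# 32-bit IEEE float, strip-organized. No R TIFF package is assumed.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L
)

#' Write a grayscale multi-page TIFF
#'
#' Writes a list of numeric matrices as an uncompressed little-endian
#' baseline TIFF, one page per frame.
#'
#' @param frames a numeric matrix or list of matrices (rows x cols), all of
#'   identical dimension. Values are rounded and clamped for integer modes.
#' @param path output file path.
#' @param bits bits per sample: 8 or 16 (unsigned integer) or 32 (IEEE
#'   float; `NA` stored as NaN).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, bits = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, bits %in% c(8L, 16L, 32L))
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("all frames must have identical shape")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  bytes_px <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_size <- nr * nc * bytes_px
  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  offset <- 8L
  first_ifd <- offset + data_size
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (i in seq_along(frames)) {
    m <- frames[[i]]
    vals <- as.vector(t(m))  # TIFF row-major order
    if (bits == 32L) {
      vals[is.na(vals)] <- NaN
      writeBin(vals, con, size = 4, endian = "little")
    } else {
      top <- 2^bits - 1
      vals <- pmin(pmax(round(vals), 0), top)
      vals[is.na(vals)] <- 0
      if (bits == 8L) {
        writeBin(as.raw(vals), con)
      } else {
        # writeBin(size=2) is signed; fold into [-32768, 32767]
        v <- as.integer(vals)
        v[v > 32767L] <- v[v > 32767L] - 65536L
        writeBin(v, con, size = 2, endian = "little")
      }
    }
    data_off <- offset
    ifd_off <- data_off + data_size
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 3L, 1L, nc)
    entry(257L, 3L, 1L, nr)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)           # no compression
    entry(262L, 3L, 1L, 1L)           # BlackIsZero
    entry(273L, 4L, 1L, data_off)     # single strip
    entry(277L, 3L, 1L, 1L)
    entry(278L, 3L, 1L, nr)
    entry(279L, 4L, 1L, data_size)
    entry(339L, 3L, 1L, if (bits == 32L) 3L else 1L)
    nxt <- if (i < length(frames)) ifd_off + ifd_size + data_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Reads uncompressed single-sample TIFFs (8/16-bit unsigned or 32-bit
#' float), either byte order, arbitrary strip layout.
#'
#' @param path file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4, endian = endian)
  }
  magic <- rint(2, 2)
  if (magic != 42L) stop("not a TIFF file: ", path)
  type_size <- c(1L, 1L, 2L, 4L)  # BYTE, ASCII, SHORT, LONG

  frames <- list()
  ifd_off <- rint(4, 4)
  while (ifd_off != 0) {
    n_entries <- rint(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rint(eo, 2)
      type <- rint(eo + 2, 2)
      count <- rint(eo + 4, 4)
      if (!(type %in% c(1L, 3L, 4L))) next
      sz <- type_size[type]
      voff <- if (sz * count <= 4) eo + 8 else rint(eo + 8, 4)
      tags[[as.character(tag)]] <- rint(voff, sz, count)
    }
    need <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing tag ", t, " in ", path)
        default
      } else v
    }
    if (need(259L, 1L) != 1L) stop("compressed TIFF not supported: ", path)
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 8L)
    fmt <- need(339L, 1L)
    offs <- need(273L)
    cnts <- need(279L, h * w * bits / 8)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 1, signed = FALSE))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 2, signed = FALSE,
                         endian = endian))
    } else if (bits == 32L && fmt == 3L) {
      readBin(buf, "double", n = w * h, size = 4, endian = endian)
    } else stop("unsupported TIFF pixel type (bits=", bits, ", fmt=", fmt,
                ") in ", path)
    frames[[length(frames) + 1]] <- matrix(vals, nrow = h, ncol = w,
                                           byrow = TRUE)
    ifd_off <- rint(ifd_off + 2 + n_entries * 12, 4)
  }
  frames
}
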