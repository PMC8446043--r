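#' Minimal baseline TIFF input/output
#'
#' The package ships its own reader/writer for uncompressed single-channel
#' (grayscale) TIFF stacks: 8- and 16-bit unsigned integer and 32-bit IEEE
#' float samples, one sample per pixel, single- or multi-strip pages.  This
#' covers everything a fluorescence time-lapse export needs; compressed,
#' tiled, palette or multi-channel files are rejected with an informative
#' error.  Written files are little-endian, one strip per page; both byte
#' orders are accepted on read.
#'
#' @name tiff-io
#' @keywords internal
NULL

.tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

# TIFF type sizes: 1=BYTE 2=ASCII 3=SHORT 4=LONG 5=RATIONAL ... 11=FLOAT
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.read_uint <- function(raw, offset, size, endian) {
  # offset is 0-based byte offset into `raw`
  bytes <- as.integer(raw[(offset + 1L):(offset + size)])
  if (endian == "big") bytes <- rev(bytes)
  sum(bytes * 256^(seq_len(size) - 1L))
}

#' Read a grayscale TIFF stack
#'
#' @param path Path to a single- or multi-page TIFF file.
#' @return A list with `pages` (list of numeric matrices, row = image row),
#'   `bits` and `sample_format` of the first page.
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("Not a TIFF file (too short): ", path)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("Not a TIFF file (bad byte-order mark): ", path))
  if (.read_uint(raw, 2L, 2L, endian) != 42L)
    stop("Not a TIFF file (magic != 42): ", path)

  ifd_offset <- .read_uint(raw, 4L, 4L, endian)
  pages <- list()
  bits <- NULL
  fmt <- NULL
  while (ifd_offset != 0L) {
    n_entries <- .read_uint(raw, ifd_offset, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      base <- ifd_offset + 2L + (i - 1L) * 12L
      id <- .read_uint(raw, base, 2L, endian)
      type <- .read_uint(raw, base + 2L, 2L, endian)
      count <- .read_uint(raw, base + 4L, 4L, endian)
      tsize <- if (type >= 1L && type <= 12L) .tiff_type_size[type] else 1L
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) base + 8L else .read_uint(raw, base + 8L, 4L, endian)
      vals <- if (type %in% c(3L, 4L)) {
        vapply(seq_len(count) - 1L, function(k)
          .read_uint(raw, voff + k * tsize, tsize, endian), numeric(1))
      } else NULL
      tags[[as.character(id)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    pbits <- g(258, 1)[1]
    compression <- g(259, 1)[1]
    photometric <- g(262, 1)[1]
    spp <- g(277, 1)[1]
    pfmt <- g(339, 1)[1]
    if (compression != 1) stop("Unsupported TIFF: compressed (tag 259 = ",
                               compression, "); only uncompressed is supported")
    if (spp != 1) stop("Unsupported TIFF: ", spp,
                       " samples per pixel (RGB/multichannel); grayscale required")
    if (!photometric %in% c(0, 1)) stop("Unsupported TIFF photometric: ", photometric)
    if (!(pbits %in% c(8, 16) && pfmt == 1) && !(pbits == 32 && pfmt == 3))
      stop("Unsupported TIFF sample type: ", pbits, "-bit, format ", pfmt)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep(width * height * pbits / 8 / length(offsets),
                                       length(offsets))
    buf <- raw(0)
    for (s in seq_along(offsets))
      buf <- c(buf, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
    n_px <- width * height
    vals <- if (pbits == 32) {
      readBin(buf, "double", n = n_px, size = 4L, endian = endian)
    } else {
      readBin(buf, "integer", n = n_px, size = pbits / 8L,
              signed = FALSE, endian = endian)
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = height,
                                          ncol = width, byrow = TRUE)
    if (is.null(bits)) { bits <- pbits; fmt <- pfmt }
    ifd_offset <- .read_uint(raw, ifd_offset + 2L + n_entries * 12L, 4L, endian)
  }
  if (!length(pages)) stop("TIFF file contains no pages: ", path)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("TIFF pages have inconsistent shapes")
  list(pages = pages, bits = bits, sample_format = fmt)
}

.uint_to_raw <- function(v, size) {
  v <- round(v)
  out <- raw(length(v) * size)
  for (k in seq_len(size)) {
    out[seq(k, length(out), by = size)] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

#' Write a grayscale TIFF stack
#'
#' @param pages List of numeric matrices (all the same shape) or a 3-D array
#'   indexed (time, row, col).
#' @param path Output path.
#' @param bits 8, 16 (unsigned integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(pages, path, bits = 32) {
  if (is.array(pages) && length(dim(pages)) == 3L)
    pages <- lapply(seq_len(dim(pages)[1]), function(i) pages[i, , ])
  stopifnot(length(pages) >= 1L, bits %in% c(8, 16, 32))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (bits < 32) {
    rng <- range(unlist(lapply(pages, range)))
    if (rng[1] < 0 || rng[2] > 2^bits - 1)
      stop("Intensities outside [0, ", 2^bits - 1, "] cannot be stored as ",
           bits, "-bit; use bits = 32")
  }
  fmt <- if (bits == 32) 3L else 1L
  bytes_per_px <- bits / 8L
  strip_bytes <- w * h * bytes_per_px
  n <- length(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.uint_to_raw(42, 2), con)
  # layout: header(8) | page strips | IFDs
  first_strip <- 8L
  ifd_start <- first_strip + n * strip_bytes
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  writeBin(.uint_to_raw(ifd_start, 4), con)  # offset of first IFD
  for (i in seq_len(n)) {
    m <- t(pages[[i]])  # row-major order
    if (bits == 32) {
      writeBin(as.numeric(m), con, size = 4L, endian = "little")
    } else {
      writeBin(.uint_to_raw(as.numeric(m), bytes_per_px), con)
    }
  }
  for (i in seq_len(n)) {
    strip_off <- first_strip + (i - 1L) * strip_bytes
    next_ifd <- if (i < n) ifd_start + i * ifd_size else 0L
    writeBin(.uint_to_raw(n_tags, 2), con)
    wtag <- function(id, type, count, value) {
      writeBin(.uint_to_raw(id, 2), con)
      writeBin(.uint_to_raw(type, 2), con)
      writeBin(.uint_to_raw(count, 4), con)
      writeBin(.uint_to_raw(value, 4), con)  # always fits in 4 bytes here
    }
    wtag(256, 4, 1, w)            # ImageWidth
    wtag(257, 4, 1, h)            # ImageLength
    wtag(258, 3, 1, bits)         # BitsPerSample
    wtag(259, 3, 1, 1)            # Compression = none
    wtag(262, 3, 1, 1)            # Photometric = BlackIsZero
    wtag(273, 4, 1, strip_off)    # StripOffsets
    wtag(278, 4, 1, h)            # RowsPerStrip
    wtag(279, 4, 1, strip_bytes)  # StripByteCounts
    wtag(339, 3, 1, fmt)          # SampleFormat
    writeBin(.uint_to_raw(next_ifd, 4), con)
  }
  invisible(path)
}
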