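# Minimal baseline TIFF I/O.
#
# No TIFF reader is available in the supported dependency set, so the
# package carries its own implementation of the small corner of the format
# it needs for interchange: uncompressed grayscale multi-page TIFF,
# 8/16-bit unsigned or 32-bit float samples, 1 sample/pixel (intensity) or
# 2 samples/pixel (real+imaginary, chunky layout). Both byte orders are
# read; files are written little-endian.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

.u16raw <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, (x %/% 256L) %% 256L)))
}

.u32raw <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256,
                         (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

.rd_uint <- function(bytes, little) {
  v <- as.numeric(bytes)
  p <- if (little) 256^(seq_along(v) - 1) else rev(256^(seq_along(v) - 1))
  sum(v * p)
}

.tiff_entry <- function(tag, type, count, value_field) {
  c(.u16raw(tag), .u16raw(type), .u32raw(count), value_field)
}

#' Read the pages of a multi-page TIFF
#'
#' Low-level reader for uncompressed grayscale baseline TIFF. Each page is
#' returned as a numeric matrix `[rows, cols]`; two-sample (complex) pages
#' are returned as complex matrices (sample 1 = real, sample 2 =
#' imaginary).
#'
#' @param path file path.
#' @return A list with elements `pages` (list of matrices), `bits`
#'   (bits per sample) and `sample_format` (1 = unsigned int, 3 = float).
#' @export
read_tiff_pages <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L) stop("unreadable TIFF: file too short")
  order_tag <- rawToChar(bytes[1:2])
  little <- identical(order_tag, "II")
  if (!little && !identical(order_tag, "MM"))
    stop("unreadable TIFF: bad byte-order mark")
  if (.rd_uint(bytes[3:4], little) != 42)
    stop("unreadable TIFF: bad magic number")
  endian <- if (little) "little" else "big"

  read_values <- function(type, count, field) {
    size <- TIFF_TYPE_SIZE[[as.character(type)]]
    nbytes <- size * count
    src <- if (nbytes <= 4L) field[seq_len(nbytes)] else {
      off <- .rd_uint(field, little)
      bytes[(off + 1):(off + nbytes)]
    }
    if (type %in% c(3, 4, 1)) {
      vapply(seq_len(count), function(i) {
        .rd_uint(src[((i - 1) * size + 1):(i * size)], little)
      }, numeric(1))
    } else if (type == 11) {
      readBin(src, "numeric", n = count, size = 4L, endian = endian)
    } else NULL
  }

  pages <- list()
  bits_seen <- integer(0)
  fmt_seen <- integer(0)
  ifd_off <- .rd_uint(bytes[5:8], little)
  while (ifd_off != 0) {
    n_entries <- .rd_uint(bytes[(ifd_off + 1):(ifd_off + 2)], little)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- .rd_uint(bytes[(base + 1):(base + 2)], little)
      type <- .rd_uint(bytes[(base + 3):(base + 4)], little)
      count <- .rd_uint(bytes[(base + 5):(base + 8)], little)
      field <- bytes[(base + 9):(base + 12)]
      tags[[as.character(tag)]] <- read_values(type, count, field)
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    if (is.null(width) || is.null(height)) stop("unreadable TIFF: no size tags")
    compression <- if (is.null(tags[["259"]])) 1 else tags[["259"]][1]
    if (compression != 1) stop("unsupported TIFF: compressed data")
    bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]][1]
    spp <- if (is.null(tags[["277"]])) 1 else tags[["277"]][1]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
    depth <- if (is.null(tags[["32997"]])) 1 else tags[["32997"]][1]  # ImageDepth
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offs)) stop("unreadable TIFF: no strip offsets")
    if (is.null(counts)) counts <- width * height * spp * bits / 8
    raw_data <- raw(0)
    for (s in seq_along(offs))
      raw_data <- c(raw_data, bytes[(offs[s] + 1):(offs[s] + counts[s])])
    n_samples <- width * height * depth * spp
    vals <- if (fmt == 3) {
      if (bits != 32) stop("unsupported TIFF: non-32-bit float")
      readBin(raw_data, "numeric", n = n_samples, size = 4L, endian = endian)
    } else if (bits == 8) {
      as.numeric(as.integer(raw_data[seq_len(n_samples)]))
    } else if (bits == 16) {
      m <- matrix(as.numeric(raw_data[seq_len(2 * n_samples)]), nrow = 2L)
      if (little) m[1, ] + 256 * m[2, ] else 256 * m[1, ] + m[2, ]
    } else stop("unsupported TIFF: bits per sample ", bits)
    per_page <- width * height * spp
    for (dpl in seq_len(depth)) {
      pv <- vals[((dpl - 1) * per_page + 1):(dpl * per_page)]
      page <- if (spp == 2) {
        re <- pv[seq(1, length(pv), by = 2)]
        im <- pv[seq(2, length(pv), by = 2)]
        matrix(complex(real = re, imaginary = im), nrow = height,
               ncol = width, byrow = TRUE)
      } else {
        matrix(pv, nrow = height, ncol = width, byrow = TRUE)
      }
      pages[[length(pages) + 1L]] <- page
      bits_seen <- c(bits_seen, as.integer(bits))
      fmt_seen <- c(fmt_seen, as.integer(fmt))
    }
    next_off_base <- ifd_off + 2 + n_entries * 12
    ifd_off <- .rd_uint(bytes[(next_off_base + 1):(next_off_base + 4)], little)
  }
  if (length(unique(bits_seen)) > 1L)
    stop("mixed bit depths across TIFF pages")
  list(pages = pages, bits = bits_seen[1], sample_format = fmt_seen[1])
}

#' Write matrices as a multi-page TIFF
#'
#' @param pages list of numeric matrices (all the same extent), or complex
#'   matrices for two-channel output.
#' @param path output file path.
#' @param format `"uint8"`, `"uint16"` or `"float32"`; `"auto"` picks the
#'   narrowest lossless representation.
#' @return `path`, invisibly.
#' @export
write_tiff_pages <- function(pages, path,
                             format = c("auto", "uint8", "uint16", "float32")) {
  format <- match.arg(format)
  if (!length(pages)) stop("no pages to write")
  complex_data <- is.complex(pages[[1]])
  if (complex_data) format <- "float32"
  if (format == "auto") {
    vals <- unlist(lapply(pages, as.vector))
    format <- if (all(vals == round(vals)) && min(vals) >= 0) {
      if (max(vals) <= 255) "uint8" else if (max(vals) <= 65535) "uint16"
      else "float32"
    } else "float32"
  }
  bits <- switch(format, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (format == "float32") 3L else 1L
  spp <- if (complex_data) 2L else 1L
  height <- nrow(pages[[1]]); width <- ncol(pages[[1]])

  encode_page <- function(m) {
    if (!identical(dim(m), c(height, width)))
      stop("all pages must share one extent")
    v <- as.vector(t(m))  # row-major
    if (complex_data) {
      v <- as.vector(rbind(Re(v), Im(v)))
    }
    switch(format,
      uint8 = as.raw(as.integer(round(v))),
      uint16 = .u16raw(v),
      float32 = writeBin(as.numeric(v), raw(), size = 4L, endian = "little"))
  }

  blobs <- lapply(pages, encode_page)
  n_pages <- length(pages)
  data_offsets <- numeric(n_pages)
  off <- 8
  for (p in seq_len(n_pages)) {
    data_offsets[p] <- off
    off <- off + length(blobs[[p]])
  }
  if (off %% 2 == 1) off <- off + 1  # word-align IFDs
  ifd_offsets <- numeric(n_pages)
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  for (p in seq_len(n_pages)) ifd_offsets[p] <- off + (p - 1) * ifd_size

  short_field <- function(...) {
    v <- c(...)
    out <- .u16raw(v)
    c(out, raw(4 - length(out)))
  }
  make_ifd <- function(p) {
    nxt <- if (p < n_pages) ifd_offsets[p + 1] else 0
    bps_field <- if (spp == 2) short_field(bits, bits) else short_field(bits)
    sf_field <- if (spp == 2) short_field(fmt, fmt) else short_field(fmt)
    c(.u16raw(n_entries),
      .tiff_entry(256, 4, 1, .u32raw(width)),
      .tiff_entry(257, 4, 1, .u32raw(height)),
      .tiff_entry(258, 3, spp, bps_field),
      .tiff_entry(259, 3, 1, short_field(1)),
      .tiff_entry(262, 3, 1, short_field(1)),
      .tiff_entry(273, 4, 1, .u32raw(data_offsets[p])),
      .tiff_entry(277, 3, 1, short_field(spp)),
      .tiff_entry(279, 4, 1, .u32raw(length(blobs[[p]]))),
      .tiff_entry(339, 3, spp, sf_field),
      .u32raw(nxt))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16raw(42), .u32raw(ifd_offsets[1])), con)
  pos <- 8
  for (p in seq_len(n_pages)) {
    writeBin(blobs[[p]], con)
    pos <- pos + length(blobs[[p]])
  }
  if (pos %% 2 == 1) writeBin(raw(1), con)
  for (p in seq_len(n_pages)) writeBin(make_ifd(p), con)
  invisible(path)
}

#' Read a 4D OCT volume from a multi-page TIFF
#'
#' Pages are expected in acquisition order with repeated frames
#' interleaved: page `(z - 1) * t + f` holds frame `f` of B-scan `z`.
#' Each page stores a B-scan as a `[y, x]` matrix (rows are depth).
#'
#' @param path TIFF file path.
#' @param layout list describing page ordering and metadata:
#'   `n_frames_t` (frames per position, default 1), and optionally
#'   `dx_um`, `dy_um`, `dz_um`, `bit_depth`. When `NULL`, a JSON sidecar
#'   `<path>.json` is read if present.
#' @return An [oct_volume4d()] (or [complex_volume4d()] for two-channel
#'   float input).
#' @export
read_volume <- function(path, layout = NULL) {
  if (is.null(layout)) {
    sidecar <- paste0(path, ".json")
    layout <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  }
  t_frames <- as.integer(layout$n_frames_t %||% 1L)
  if (t_frames < 1L) stop("layout n_frames_t must be >= 1")
  tif <- read_tiff_pages(path)
  n_pages <- length(tif$pages)
  if (n_pages %% t_frames != 0L)
    stop(sprintf("page count %d is not divisible by n_frames_t = %d",
                 n_pages, t_frames))
  nz <- n_pages %/% t_frames
  ny <- nrow(tif$pages[[1]]); nx <- ncol(tif$pages[[1]])
  complex_data <- is.complex(tif$pages[[1]])
  data <- array(if (complex_data) complex(1) else 0,
                dim = c(nx, ny, t_frames, nz))
  for (p in seq_len(n_pages)) {
    f <- (p - 1L) %% t_frames + 1L
    z <- (p - 1L) %/% t_frames + 1L
    data[, , f, z] <- t(tif$pages[[p]])
  }
  dx <- as.numeric(layout$dx_um %||% 1.4)
  dy <- as.numeric(layout$dy_um %||% 1.9)
  dz <- as.numeric(layout$dz_um %||% 1.4)
  if (complex_data)
    return(complex_volume4d(data, dx = dx, dy = dy, dz = dz))
  bit_depth <- as.integer(layout$bit_depth %||%
                            (if (tif$bits == 16) 16L else 8L))
  if (tif$sample_format == 3 && is.null(layout$bit_depth)) bit_depth <- 16L
  oct_volume4d(data, dx = dx, dy = dy, dz = dz, bit_depth = bit_depth)
}

#' Write a volume or en-face stack as a multi-page TIFF
#'
#' One page per leading slice: a [volume3d()] writes one `[y, x]` page per
#' B-scan index `z`; an [enface_stack()] writes one `[z, x]` page per depth
#' index `y`; an [oct_volume4d()] or [complex_volume4d()] writes frames
#' interleaved as in [read_volume()]. Integer data round-trips bit-exactly.
#'
#' @param x object to write.
#' @param path output TIFF path.
#' @param format passed to [write_tiff_pages()].
#' @param sidecar write a JSON metadata sidecar alongside (default TRUE for
#'   4D volumes).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, format = "auto", sidecar = inherits(x, c("oct_volume4d", "complex_volume4d"))) {
  pages <- if (inherits(x, "volume3d")) {
    lapply(seq_len(dim(x$data)[3]), function(k) t(x$data[, , k]))
  } else if (inherits(x, "enface_stack")) {
    lapply(seq_len(dim(x$data)[3]), function(j) t(x$data[, , j]))
  } else if (inherits(x, c("oct_volume4d", "complex_volume4d"))) {
    d <- dim(x$data)
    unlist(lapply(seq_len(d[4]), function(z) {
      lapply(seq_len(d[3]), function(f) t(x$data[, , f, z]))
    }), recursive = FALSE)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[3]), function(k) t(x[, , k]))
  } else if (is.matrix(x)) {
    list(t(x))
  } else stop("unsupported object for write_stack()")
  write_tiff_pages(pages, path, format = format)
  if (isTRUE(sidecar)) {
    meta <- list(dx_um = x$dx, dy_um = x$dy, dz_um = x$dz,
                 n_frames_t = if (inherits(x, c("oct_volume4d", "complex_volume4d"))) dim(x$data)[3] else 1L,
                 bit_depth = x$bit_depth %||% 16L)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
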