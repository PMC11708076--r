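# Minimal, dependency-free image writers: 8-bit RGB PNG (stored-deflate
# zlib stream) for previews and uncompressed 32-bit float grayscale TIFF for
# cone-catch channels. No imaging package is required at runtime; output is
# deterministic byte-for-byte.

# ---- checksums -------------------------------------------------------------

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!exists("tab", envir = crc32_env, inherits = FALSE)) {
    tab <- integer(256)
    poly <- -306674912L  # 0xEDB88320
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), poly)
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tab[i + 1L] <- c
    }
    assign("tab", tab, envir = crc32_env)
  }
  get("tab", envir = crc32_env)
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

adler32 <- function(bytes) {
  s1 <- 1; s2 <- 0
  ints <- as.numeric(bytes)
  n <- length(ints)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + 4095L)
    chunk <- ints[i:j]
    cs <- cumsum(chunk)
    s2 <- (s2 + length(chunk) * s1 + sum(cs)) %% 65521
    s1 <- (s1 + cs[length(cs)]) %% 65521
    i <- j + 1L
  }
  s2 * 65536 + s1
}

int_to_raw_be <- function(x, width = 4L) {
  x <- as.numeric(x) %% 2^(8 * width)
  out <- raw(width)
  for (i in width:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

int_to_raw_le <- function(x, width = 4L) {
  rev(int_to_raw_be(x, width))
}

# ---- PNG -------------------------------------------------------------------

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_raw_be(length(data)), body,
    int_to_raw_be(crc32(body) %% 2^32))
}

# zlib stream with stored (uncompressed) deflate blocks
zlib_stored <- function(data) {
  n <- length(data)
  blocks <- raw(0)
  i <- 1L
  repeat {
    j <- min(n, i + 65534L)
    len <- if (n == 0L) 0L else j - i + 1L
    final <- if (j >= n) as.raw(1L) else as.raw(0L)
    blocks <- c(blocks, final,
                int_to_raw_le(len, 2L), int_to_raw_le(65535 - len, 2L),
                if (len > 0L) data[i:j])
    if (j >= n) break
    i <- j + 1L
  }
  c(as.raw(c(0x78, 0x01)), blocks, int_to_raw_be(adler32(data)))
}

#' Write an 8-bit RGB PNG
#'
#' Deterministic minimal PNG writer (stored-deflate zlib stream, filter 0).
#'
#' @param img Integer/numeric array `[rows, cols, 3]` with values in 0..255,
#'   or a matrix (written as grayscale replicated to RGB).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_png_rgb8 <- function(img, path) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
  }
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pmin(pmax(round(img), 0), 255)
  scanlines <- raw((3L * w + 1L) * h)
  pos <- 1L
  for (r in seq_len(h)) {
    row <- as.vector(rbind(px[r, , 1], px[r, , 2], px[r, , 3]))
    scanlines[pos] <- as.raw(0L)
    scanlines[(pos + 1L):(pos + 3L * w)] <- as.raw(row)
    pos <- pos + 3L * w + 1L
  }
  ihdr <- c(int_to_raw_be(w), int_to_raw_be(h),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stored(scanlines)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# ---- TIFF ------------------------------------------------------------------

tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  c(int_to_raw_le(tag, 2L), int_to_raw_le(type, 2L),
    int_to_raw_le(count, 4L), value_raw, raw(4L - length(value_raw)))
}

#' Write a 32-bit float grayscale TIFF
#'
#' Single-strip, uncompressed, little-endian IEEE-float TIFF — the format
#' used for exported cone-catch channels.
#'
#' @param mat Numeric matrix (rows = image rows).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tiff_gray32f <- function(mat, path) {
  stopifnot(is.matrix(mat))
  h <- nrow(mat); w <- ncol(mat)
  n_entries <- 10L
  data_offset <- 8L + 2L + 12L * n_entries + 4L
  entries <- c(
    tiff_entry(256L, 4L, 1L, int_to_raw_le(w)),              # ImageWidth
    tiff_entry(257L, 4L, 1L, int_to_raw_le(h)),              # ImageLength
    tiff_entry(258L, 3L, 1L, int_to_raw_le(32L, 2L)),        # BitsPerSample
    tiff_entry(259L, 3L, 1L, int_to_raw_le(1L, 2L)),         # Compression
    tiff_entry(262L, 3L, 1L, int_to_raw_le(1L, 2L)),         # BlackIsZero
    tiff_entry(273L, 4L, 1L, int_to_raw_le(data_offset)),    # StripOffsets
    tiff_entry(277L, 3L, 1L, int_to_raw_le(1L, 2L)),         # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, int_to_raw_le(h)),              # RowsPerStrip
    tiff_entry(279L, 4L, 1L, int_to_raw_le(4L * w * h)),     # StripByteCounts
    tiff_entry(339L, 3L, 1L, int_to_raw_le(3L, 2L)))         # SampleFormat
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), int_to_raw_le(42L, 2L), int_to_raw_le(8L)),
           con)
  writeBin(int_to_raw_le(n_entries, 2L), con)
  writeBin(entries, con)
  writeBin(int_to_raw_le(0L), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 32-bit float grayscale TIFF written by [write_tiff_gray32f()]
#'
#' A minimal reader for round-trip verification; it understands exactly the
#' single-strip little-endian layout this package writes.
#'
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_tiff_gray32f <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:2], charToRaw("II"))) {
    stop("not a little-endian TIFF")
  }
  ifd_offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, ifd_offset)
  n <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  tags <- list()
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    type <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    value_raw <- readBin(con, "raw", 4L)
    value <- if (type == 3L) {
      sum(as.integer(value_raw[1:2]) * c(1, 256))
    } else {
      sum(as.numeric(as.integer(value_raw)) * 256^(0:3))
    }
    tags[[as.character(tag)]] <- value
  }
  w <- tags[["256"]]; h <- tags[["257"]]
  if (!identical(tags[["339"]], 3) && !identical(tags[["339"]], 3L)) {
    stop("not a float TIFF")
  }
  seek(con, tags[["273"]])
  vals <- readBin(con, "numeric", w * h, size = 4L, endian = "little")
  matrix(vals, nrow = h, byrow = TRUE)
}
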