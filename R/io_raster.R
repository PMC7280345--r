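# Raster I/O with explicit bit-depth handling. Integer PNG/TIFF reads go
# through the png/tiff packages. Two writers are implemented here because
# no installed package provides them: 16-bit grayscale PNG (png only
# writes 8-bit) and 32-bit float grayscale TIFF (tiff clamps floats to
# [0,1]). Both write the minimal standard-conformant layout.

u32be <- function(x) {
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(x, 255L)))
}

# Table-driven CRC-32 (ISO 3309, as PNG requires) on signed 32-bit
# integers; bitwShiftR is a zero-fill shift so the bit patterns work out.
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
          } else bitwShiftR(c, 1L)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32_raw <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  u32be(bitwXor(crc, -1L))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, crc32_raw(body))
}

# Minimal grayscale PNG writer, bit depth 8 or 16, no interlace.
write_png_gray <- function(m, path, bits) {
  H <- nrow(m); W <- ncol(m)
  px <- as.integer(t(m))
  if (bits == 16L) {
    scan <- raw(H * (1L + 2L * W))
    line <- matrix(raw(2L * W), nrow = 2L * W, ncol = H)
    pxm <- matrix(px, nrow = W, ncol = H)  # column h = scanline h
    line[c(TRUE, FALSE), ] <- as.raw(bitwShiftR(pxm, 8L))
    line[c(FALSE, TRUE), ] <- as.raw(bitwAnd(pxm, 255L))
    scan <- as.vector(rbind(raw(H), line))  # filter byte 0 per line
  } else {
    pxm <- matrix(as.raw(px), nrow = W, ncol = H)
    scan <- as.vector(rbind(raw(H), pxm))
  }
  ihdr <- c(u32be(W), u32be(H), as.raw(c(bits, 0L, 0L, 0L, 0L)))
  # memCompress(type = "gzip") emits an RFC 1950 zlib stream, which is
  # exactly the IDAT payload format
  idat <- memCompress(scan, type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

tiff_ifd_entry <- function(tag, type, count, value) {
  c(u16le(tag), u16le(type), u32le(count), u32le(value))
}

# Minimal single-strip 32-bit float grayscale TIFF (little endian).
write_tiff_float <- function(m, path) {
  H <- nrow(m); W <- ncol(m)
  data <- writeBin(as.numeric(t(m)), raw(), size = 4L, endian = "little")
  ifd_offset <- 8L + length(data)
  entries <- c(
    tiff_ifd_entry(256L, 3L, 1L, W),                  # ImageWidth
    tiff_ifd_entry(257L, 3L, 1L, H),                  # ImageLength
    tiff_ifd_entry(258L, 3L, 1L, 32L),                # BitsPerSample
    tiff_ifd_entry(259L, 3L, 1L, 1L),                 # Compression: none
    tiff_ifd_entry(262L, 3L, 1L, 1L),                 # Photometric: BlackIsZero
    tiff_ifd_entry(273L, 4L, 1L, 8L),                 # StripOffsets
    tiff_ifd_entry(277L, 3L, 1L, 1L),                 # SamplesPerPixel
    tiff_ifd_entry(278L, 3L, 1L, H),                  # RowsPerStrip
    tiff_ifd_entry(279L, 4L, 1L, length(data)),       # StripByteCounts
    tiff_ifd_entry(339L, 3L, 1L, 3L)                  # SampleFormat: IEEE float
  )
  out <- c(charToRaw("II"), u16le(42L), u32le(ifd_offset),
           data, u16le(10L), entries, u32le(0L))
  writeBin(out, path)
  invisible(path)
}

tiff_read_tags <- function(b) {
  if (rawToChar(b[1:2]) != "II") return(NULL)  # only little-endian parsed here
  ifd <- rd_u32(b, 5L)
  n <- rd_u16(b, ifd + 1L)
  tags <- list()
  for (i in seq_len(n)) {
    at <- ifd + 3L + (i - 1L) * 12L
    tags[[as.character(rd_u16(b, at))]] <-
      list(type = rd_u16(b, at + 2L), count = rd_u32(b, at + 4L),
           value = rd_u32(b, at + 8L))
  }
  tags
}

read_tiff_float <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  tags <- tiff_read_tags(b)
  W <- tags[["256"]]$value; H <- tags[["257"]]$value
  off <- tags[["273"]]$value
  if (tags[["259"]]$value != 1L) stop("compressed float TIFF unsupported")
  con <- rawConnection(b[(off + 1L):(off + 4L * W * H)])
  on.exit(close(con))
  v <- readBin(con, "numeric", n = W * H, size = 4L, endian = "little")
  matrix(v, nrow = H, ncol = W, byrow = TRUE)
}

is_float_tiff <- function(path) {
  b <- readBin(path, "raw", n = min(file.size(path), 65536L))
  tags <- tryCatch(tiff_read_tags(b), error = function(e) NULL)
  !is.null(tags) && !is.null(tags[["339"]]) && tags[["339"]]$value == 3L
}

raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported raster extension: .", ext)
}

#' Read a PNG/TIFF raster as a radiograph
#'
#' Integer rasters come back losslessly as a `radiograph` whose bit depth
#' is the file's sample depth (8 or 16); 32-bit float TIFFs (as written by
#' [write_raster()] for real-valued maps) come back as a `feature_map`.
#'
#' @param path file path (.png, .tif, .tiff).
#' @return a `radiograph`, or a `feature_map` for float TIFF.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- raster_format(path)
  if (fmt == "png") {
    bits <- png_bit_depth(path)
    if (!bits %in% c(8L, 16L)) stop("unsupported PNG bit depth: ", bits)
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) stop("color payload unsupported: ", path)
    m <- round_half_up(v * (2^bits - 1))
    return(radiograph(m, bits))
  }
  if (is_float_tiff(path)) {
    return(feature_map(read_tiff_float(path),
                       provenance = list(source = path)))
  }
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3L) stop("color payload unsupported: ", path)
  bits <- if (max(v) > 255) 16L else attr(v, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(v) > 255) 16L else 8L
  radiograph(v, as.integer(bits))
}

#' Write a radiograph or feature map as PNG/TIFF
#'
#' Integer modes are lossless round-trips; out-of-range values are an
#' error, never clipped (8-bit exports of real-valued maps must go through
#' the post-processing transforms first, not silent truncation). Float
#' maps are written as 32-bit float TIFF.
#'
#' @param x a `radiograph`, `feature_map` or matrix.
#' @param path output path (.png, .tif, .tiff).
#' @param mode `"8bit"`, `"16bit"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, mode = c("8bit", "16bit", "float")) {
  mode <- match.arg(mode)
  fmt <- raster_format(path)
  m <- pixel_matrix(x)
  if (mode == "float") {
    if (fmt != "tiff") stop("float maps are written as 32-bit TIFF, not PNG")
    write_tiff_float(m, path)
    return(invisible(path))
  }
  top <- if (mode == "8bit") 255 else 65535
  if (any(m != round(m))) {
    stop("non-integer values cannot be written in ", mode,
         " mode; post-process the map first")
  }
  if (min(m) < 0 || max(m) > top) {
    stop("values outside [0, ", top, "] cannot be written in ", mode,
         " mode (range [", min(m), ", ", max(m), "])")
  }
  if (fmt == "png") {
    if (mode == "8bit") png::writePNG(m / 255, path)
    else write_png_gray(m, path, 16L)
  } else {
    tiff::writeTIFF(m / top, path,
                    bits.per.sample = if (mode == "8bit") 8L else 16L,
                    compression = "none")
  }
  invisible(path)
}
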