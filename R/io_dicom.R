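# Minimal single-frame monochrome DICOM support (explicit VR little
# endian, uncompressed), sufficient for intraoral radiographs: 8/12/16-bit
# grayscale pixel data, photometric interpretation, pixel spacing. 12-bit
# pixels travel in 16-bit containers; validation is against BitsStored,
# never the container width. No sequences, no multi-frame, no networking.

u16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
u32le <- function(x) {
  as.raw(c(bitwAnd(x, 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 24L), 255L)))
}
rd_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
rd_u32 <- function(b, i) {
  as.integer(b[i]) + 256 * as.integer(b[i + 1L]) +
    65536 * as.integer(b[i + 2L]) + 16777216 * as.integer(b[i + 3L])
}

dcm_element <- function(group, elem, vr, value) {
  if (length(value) %% 2L == 1L) {
    value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "UT", "UN", "SQ")) {
    c(head, as.raw(c(0L, 0L)), u32le(length(value)), value)
  } else {
    if (length(value) > 65535L) stop("element too long for a short VR")
    c(head, u16le(length(value)), value)
  }
}

dcm_str <- function(s) charToRaw(s)

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

#' Write a radiograph as single-frame monochrome DICOM
#'
#' Explicit VR little endian, uncompressed, MONOCHROME2 (higher = denser).
#' 12-bit images are stored with BitsAllocated 16 / BitsStored 12, as
#' detectors do.
#'
#' @param image a `radiograph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path) {
  stopifnot(inherits(image, "radiograph"))
  m <- image$pixels
  bits <- image$bit_depth
  alloc <- if (bits == 8L) 8L else 16L

  meta <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0L, 1L))),
    dcm_element(2L, 2L, "UI", dcm_str(SOP_CLASS_SECONDARY_CAPTURE)),
    dcm_element(2L, 3L, "UI", dcm_str("1.2.826.0.1.3680043.8.498.1")),
    dcm_element(2L, 16L, "UI", dcm_str(TRANSFER_SYNTAX_EXPLICIT_LE))
  )
  meta <- c(dcm_element(2L, 0L, "UL", u32le(length(meta))), meta)

  px <- as.integer(t(m))  # DICOM pixel data is row-major
  pix_raw <- if (alloc == 8L) {
    as.raw(px)
  } else {
    r <- raw(2L * length(px))
    r[c(TRUE, FALSE)] <- as.raw(bitwAnd(px, 255L))
    r[c(FALSE, TRUE)] <- as.raw(bitwShiftR(px, 8L))
    r
  }

  ds <- c(
    dcm_element(8L, 22L, "UI", dcm_str(SOP_CLASS_SECONDARY_CAPTURE)),
    dcm_element(8L, 24L, "UI", dcm_str("1.2.826.0.1.3680043.8.498.1")),
    dcm_element(40L, 2L, "US", u16le(1L)),
    dcm_element(40L, 4L, "CS", dcm_str("MONOCHROME2")),
    dcm_element(40L, 16L, "US", u16le(nrow(m))),
    dcm_element(40L, 17L, "US", u16le(ncol(m)))
  )
  if (!is.null(image$pixel_spacing_mm)) {
    sp <- format(image$pixel_spacing_mm, scientific = FALSE)
    ds <- c(ds, dcm_element(40L, 48L, "DS", dcm_str(paste0(sp, "\\", sp))))
  }
  ds <- c(ds,
    dcm_element(40L, 256L, "US", u16le(alloc)),
    dcm_element(40L, 257L, "US", u16le(bits)),
    dcm_element(40L, 258L, "US", u16le(bits - 1L)),
    dcm_element(40L, 259L, "US", u16le(0L)),
    dcm_element(32736L, 16L, if (alloc == 8L) "OB" else "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

parse_dicom_elements <- function(b) {
  long_vrs <- c("OB", "OW", "OF", "UT", "UN", "SQ")
  pos <- 133L  # after 128-byte preamble + "DICM"
  n <- length(b)
  out <- list()
  while (pos + 7L <= n) {
    group <- rd_u16(b, pos)
    elem <- rd_u16(b, pos + 2L)
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("cannot parse attribute (", sprintf("%04X,%04X", group, elem),
           "): implicit VR or corrupted stream is unsupported")
    }
    if (vr %in% long_vrs) {
      len <- rd_u32(b, pos + 8L)
      start <- pos + 12L
    } else {
      len <- rd_u16(b, pos + 6L)
      start <- pos + 8L
    }
    if (vr == "SQ" || len == 4294967295) {
      stop("sequence / undefined-length attribute (",
           sprintf("%04X,%04X", group, elem), ") is unsupported")
    }
    if (start + len - 1L > n) stop("truncated DICOM element")
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr,
                       value = if (len > 0) b[start:(start + len - 1L)] else raw(0))
    pos <- start + len
  }
  out
}

dcm_string_value <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value), whitespace = "[ \\x00]")
}

dcm_us_value <- function(el) if (is.null(el)) NULL else rd_u16(el$value, 1L)

#' Read a single-frame monochrome DICOM radiograph
#'
#' Accepts uncompressed explicit-VR little-endian files. The bit depth is
#' taken from BitsStored (12-bit detector data usually travels in a 16-bit
#' container); MONOCHROME1 files are inverted at read time so that higher
#' always means denser tissue; PixelSpacing is returned when present.
#' Color, multi-frame, compressed or 1/2/... non-{8,12,16}-bit payloads
#' are rejected with a diagnostic naming the offending attribute.
#'
#' @param path DICOM file path.
#' @return a `radiograph`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 160L || rawToChar(b[129:132]) != "DICM") {
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  }
  els <- parse_dicom_elements(b)

  ts <- dcm_string_value(els[["00020010"]])
  if (!is.null(ts) && ts != TRANSFER_SYNTAX_EXPLICIT_LE) {
    stop("unsupported TransferSyntaxUID ", ts,
         " (only uncompressed explicit VR little endian is supported)")
  }
  spp <- dcm_us_value(els[["00280002"]])
  photometric <- dcm_string_value(els[["00280004"]])
  if ((!is.null(spp) && spp != 1L) ||
      (!is.null(photometric) && !photometric %in% c("MONOCHROME1", "MONOCHROME2"))) {
    stop("color payload unsupported (SamplesPerPixel = ", spp,
         ", PhotometricInterpretation = ", photometric, ")")
  }
  nframes <- dcm_string_value(els[["00280008"]])
  if (!is.null(nframes) && as.integer(nframes) > 1L) {
    stop("multi-frame payload unsupported (NumberOfFrames = ", nframes, ")")
  }
  rows <- dcm_us_value(els[["00280010"]])
  cols <- dcm_us_value(els[["00280011"]])
  alloc <- dcm_us_value(els[["00280100"]])
  stored <- dcm_us_value(els[["00280101"]])
  if (is.null(rows) || is.null(cols) || is.null(alloc) || is.null(stored)) {
    stop("missing image geometry attributes (Rows/Columns/BitsAllocated/BitsStored)")
  }
  if (!stored %in% c(8L, 12L, 16L)) {
    stop("BitsStored = ", stored, " unsupported (expected 8, 12 or 16)")
  }
  if (!alloc %in% c(8L, 16L)) {
    stop("BitsAllocated = ", alloc, " unsupported")
  }
  pix <- els[["7FE00010"]]
  if (is.null(pix)) stop("missing PixelData (7FE0,0010)")
  v <- if (alloc == 8L) {
    as.integer(pix$value)
  } else {
    lo <- as.integer(pix$value[c(TRUE, FALSE)])
    hi <- as.integer(pix$value[c(FALSE, TRUE)])
    lo + 256L * hi
  }
  if (length(v) < rows * cols) stop("PixelData shorter than Rows x Columns")
  v <- v[seq_len(rows * cols)]
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  if (!is.null(photometric) && photometric == "MONOCHROME1") {
    m <- (2^stored - 1L) - m
  }

  spacing <- NULL
  sp <- dcm_string_value(els[["00280030"]])
  if (!is.null(sp) && nzchar(sp)) {
    spacing <- as.numeric(strsplit(sp, "\\\\")[[1]][1])
  }
  radiograph(m, stored, pixel_spacing_mm = spacing)
}
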