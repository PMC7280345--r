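test_that("radiograph validates its invariants", {
  expect_error(radiograph(matrix(-1L, 2, 2), 8), "non-negative")
  expect_error(radiograph(matrix(256L, 2, 2), 8), "8-bit range")
  expect_error(radiograph(matrix(0L, 2, 2), 10), "bit_depth")
  expect_error(radiograph(matrix(0L, 2, 2), 8, pixel_spacing_mm = -1), "positive")
  img <- radiograph(matrix(0:4094, 45, 91), 12, 0.018)
  expect_identical(dim(img), c(45L, 91L))
  expect_equal(img$pixel_spacing_mm, 0.018)
})

test_that("DICOM write/read round-trips exactly, including spacing", {
  set.seed(101)
  img <- radiograph(matrix(sample(0:4095, 30 * 22, TRUE), 30, 22), 12,
                    pixel_spacing_mm = 0.018)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  r <- read_dicom(f)
  expect_identical(r$pixels, img$pixels)
  expect_identical(r$bit_depth, 12L)
  expect_equal(r$pixel_spacing_mm, 0.018)

  img8 <- radiograph(matrix(sample(0:255, 64, TRUE), 8, 8), 8)
  f8 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img8, f8)
  expect_identical(read_dicom(f8)$pixels, img8$pixels)
})

test_that("an independent DICOM reader agrees with ours on a fixture", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(7)
  img <- radiograph(matrix(sample(0:4095, 20 * 16, TRUE), 20, 16), 12, 0.018)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import pydicom; d = pydicom.dcmread(%s); print(d.BitsStored, d.Rows, d.Columns, float(d.PixelSpacing[0]), int(d.pixel_array.sum()))",
    deparse(f)))), stdout = TRUE, stderr = FALSE))
  vals <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(vals[1:3]), c(12L, 20L, 16L))
  expect_equal(as.numeric(vals[4]), 0.018)
  expect_equal(as.numeric(vals[5]), sum(img$pixels))
})

test_that("MONOCHROME1 payloads are inverted to higher-is-denser", {
  img <- radiograph(matrix(c(0L, 100L, 4095L, 50L), 2, 2), 12)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  b <- readBin(f, "raw", file.size(f))
  # patch PhotometricInterpretation "MONOCHROME2" -> "MONOCHROME1"
  pat <- charToRaw("MONOCHROME2")
  idx <- which(vapply(seq_len(length(b) - length(pat) + 1L),
                      function(i) all(b[i:(i + 10L)] == pat), logical(1)))[1]
  b[idx + 10L] <- charToRaw("1")
  writeBin(b, f)
  r <- read_dicom(f)
  expect_identical(r$pixels, 4095L - img$pixels)
})

test_that("color and odd-bit DICOM payloads are rejected with diagnostics", {
  img <- radiograph(matrix(0:3, 2, 2), 8)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  b0 <- readBin(f, "raw", file.size(f))

  # SamplesPerPixel 1 -> 3 (tag 0028,0002, US value little-endian)
  b <- b0
  tagpos <- which(vapply(seq_len(length(b) - 7L), function(i) {
    all(b[i:(i + 3L)] == as.raw(c(0x28, 0x00, 0x02, 0x00)))
  }, logical(1)))[1]
  b[tagpos + 8L] <- as.raw(3L)
  f2 <- withr::local_tempfile(fileext = ".dcm"); writeBin(b, f2)
  expect_error(read_dicom(f2), "color payload unsupported")

  # BitsStored 8 -> 7 (tag 0028,0101)
  b <- b0
  tagpos <- which(vapply(seq_len(length(b) - 7L), function(i) {
    all(b[i:(i + 3L)] == as.raw(c(0x28, 0x00, 0x01, 0x01)))
  }, logical(1)))[1]
  b[tagpos + 8L] <- as.raw(7L)
  f3 <- withr::local_tempfile(fileext = ".dcm"); writeBin(b, f3)
  expect_error(read_dicom(f3), "BitsStored = 7")

  expect_error(read_dicom(withr::local_tempfile(fileext = ".dcm")), "not found")
})

test_that("integer raster round-trips are lossless for PNG and TIFF", {
  set.seed(11)
  img12 <- radiograph(matrix(sample(0:4095, 25 * 31, TRUE), 25, 31), 12)
  img8 <- bit_reduce(img12)
  for (ext in c(".png", ".tif")) {
    f16 <- withr::local_tempfile(fileext = ext)
    write_raster(img12, f16, "16bit")
    r <- read_raster(f16)
    expect_identical(r$pixels, img12$pixels)
    expect_identical(r$bit_depth, 16L)

    f8 <- withr::local_tempfile(fileext = ext)
    write_raster(img8, f8, "8bit")
    expect_identical(read_raster(f8)$pixels, img8$pixels)
  }
})

test_that("out-of-range or fractional values error rather than clip", {
  img <- radiograph(matrix(c(0L, 300L, 12L, 7L), 2, 2), 12)
  f <- withr::local_tempfile(fileext = ".png")
  expect_error(write_raster(img, f, "8bit"), "outside \\[0, 255\\]")
  expect_error(write_raster(feature_map(matrix(0.5, 2, 2)), f, "8bit"),
               "non-integer")
})

test_that("float maps round-trip through 32-bit TIFF", {
  set.seed(3)
  # values exactly representable in float32
  v <- matrix(sample(-2^20:2^20, 12 * 9, TRUE) / 256, 12, 9)
  fm <- feature_map(v)
  f <- withr::local_tempfile(fileext = ".tiff")
  write_raster(fm, f, "float")
  r <- read_raster(f)
  expect_s3_class(r, "feature_map")
  expect_identical(max(abs(r$values - v)), 0)
  expect_error(write_raster(fm, withr::local_tempfile(fileext = ".png"),
                            "float"), "32-bit TIFF")
})
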