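test_that("bit_reduce matches direct arithmetic and endpoints", {
  img <- radiograph(matrix(c(0L, 2048L, 4095L, 1L), 2, 2), 12)
  out <- bit_reduce(img, 8)
  expect_identical(as.vector(out$pixels),
                   as.integer(floor(c(0, 2048, 4095, 1) * 255 / 4095 + 0.5)))
  expect_identical(out$pixels[1, 1], 0L)
  expect_identical(out$pixels[1, 2], 255L)
  expect_identical(out$pixels[2, 1], 128L)  # round(2048 * 255 / 4095)
  expect_identical(out$bit_depth, 8L)

  img8 <- radiograph(matrix(0:3, 2, 2), 8)
  expect_identical(bit_reduce(img8, 8), img8)
  expect_error(bit_reduce(img8, 12), "exceeds")
})

test_that("histogram_equalize reproduces the CDF remap contract", {
  # a ramp with every level once is already uniform
  ramp <- radiograph(matrix(0:255, 16, 16), 8)
  expect_identical(histogram_equalize(ramp)$pixels, ramp$pixels)
  # constant image degenerates to zeros
  cst <- radiograph(matrix(77L, 5, 5), 8)
  expect_true(all(histogram_equalize(cst)$pixels == 0L))
  # two-level half/half: cdf(0) = 0.5, cdf(255) = 1 -> {0, 255}
  half <- radiograph(matrix(c(rep(0L, 128), rep(255L, 128)), 16, 16), 8)
  out <- histogram_equalize(half)
  expect_identical(out$pixels[half$pixels == 0L][1], 0L)
  expect_identical(out$pixels[half$pixels == 255L][1], 255L)
  expect_setequal(unique(as.vector(out$pixels)), c(0L, 255L))
})

test_that("bit_reduce and histogram_equalize are monotone in intensity", {
  set.seed(21)
  for (rep in 1:5) {
    img <- smooth_image_12bit(32, seed = rep)
    v <- sort(unique(as.vector(img$pixels)))
    lutb <- bit_reduce(img, 8)$pixels[order(img$pixels)]
    expect_true(all(diff(lutb) >= 0))
    luth <- histogram_equalize(img)$pixels[order(img$pixels)]
    expect_true(all(diff(luth) >= 0))
  }
})

test_that("equalization and bit-cut commute to within one gray level", {
  agree <- vapply(1:20, function(s) {
    img <- smooth_image_12bit(64, seed = s)
    a <- bit_reduce(histogram_equalize(img), 8)$pixels
    b <- histogram_equalize(bit_reduce(img, 8))$pixels
    mean(abs(a - b) <= 1L)
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("sda matches the double-loop oracle exactly for small radii", {
  set.seed(5)
  for (r in 1:3) {
    m <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    img <- radiograph(m, 8)
    got <- sda(img, sda_params(r, 0))$values
    expect_identical(got, matrix(as.numeric(oracle_sda(m, r, 0)), 32, 32))
  }
  # non-zero threshold
  m <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  got <- sda(radiograph(m, 8), sda_params(2, 10))$values
  expect_identical(got, matrix(as.numeric(oracle_sda(m, 2, 10)), 32, 32))
})

test_that("sda degenerate and bounded behaviour", {
  # constant image: every disc neighbour dominates (ties count)
  s <- sda(radiograph(matrix(9L, 12, 12), 8), sda_params(2, 0))
  expect_true(all(s$values == 12))  # offsets with m^2 + n^2 <= 4
  # single bright pixel: no neighbour reaches it
  m <- matrix(0L, 11, 11); m[6, 6] <- 200L
  s2 <- sda(radiograph(m, 8), sda_params(2, 0))
  expect_identical(s2$values[6, 6], 0)
  # raw values bounded by disc size
  set.seed(9)
  mr <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  s3 <- sda(radiograph(mr, 8), sda_params(3, 0))
  disc3 <- sum(outer((-3:3)^2, (-3:3)^2, "+") <= 9) - 1L
  expect_true(all(s3$values >= 0 & s3$values <= disc3))
  # constant raw map scales to zeros
  expect_true(all(scale_sda_to_8bit(s)$pixels == 0L))
})
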