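test_that("laws kernel invariants and constant-image response", {
  k <- laws_kernels()
  expect_identical(sum(k$L5), 16)
  expect_identical(sum(k$E5), 0)
  expect_identical(sum(k$S5), 0)
  expect_identical(sum(k$R5), 0)
  maps <- laws_maps(radiograph(matrix(120L, 20, 20), 8), window_spec(9))
  expect_length(maps, 9L)
  expect_named(maps, paste0("LAWS-F", 1:9))
  for (m in maps) expect_true(all(m$values == 0))
})

test_that("spot kernel annihilates a linear ramp", {
  # S5 row response on a horizontal arithmetic progression is a second
  # difference and vanishes away from the mirrored borders
  ramp <- radiograph(matrix(rep(10L * (0:19), each = 12), 12, 20), 8)
  maps <- laws_maps(ramp, window_spec(5))
  s5s5 <- maps[["LAWS-F9"]]$values  # S5S5
  inner <- s5s5[5:8, 9:12]
  expect_true(all(abs(inner) < 1e-9))
})

test_that("laws energies match the direct convolution oracle", {
  set.seed(61)
  m <- matrix(sample(0:255, 14 * 13, TRUE), 14, 13)
  img <- radiograph(m, 8)
  maps <- laws_maps(img, window_spec(5))
  k <- laws_kernels()
  want_e5l5 <- (oracle_laws_energy(m, k$E5, k$L5, 5) +
                oracle_laws_energy(m, k$L5, k$E5, 5)) / 2
  expect_close(maps[["LAWS-F2"]]$values, want_e5l5, 1e-9)
  want_r5r5 <- oracle_laws_energy(m, k$R5, k$R5, 5)
  expect_close(maps[["LAWS-F7"]]$values, want_r5r5, 1e-9)
  want_e5s5 <- (oracle_laws_energy(m, k$E5, k$S5, 5) +
                oracle_laws_energy(m, k$S5, k$E5, 5)) / 2
  expect_close(maps[["LAWS-F4"]]$values, want_e5s5, 1e-9)
})

test_that("laws maps are shift-equivariant away from the border", {
  set.seed(62)
  m <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  shifted <- m[c(3:40, 1:2), ]  # shift rows by 2
  a <- laws_maps(radiograph(m, 8), window_spec(5))[["LAWS-F1"]]$values
  b <- laws_maps(radiograph(shifted, 8), window_spec(5))[["LAWS-F1"]]$values
  band <- 13:26
  expect_equal(b[band - 2, band], a[band, band], tolerance = 1e-9)
})

test_that("lbp degenerate codes and single-bit case", {
  cst <- radiograph(matrix(80L, 16, 16), 8)
  expect_true(all(lbp_map(cst, lbp_params(8, 5))$values == 0))

  # bright centre, all 8 samples strictly darker at R = 2 -> 255
  m <- matrix(100L, 15, 15); m[8, 8] <- 200L
  lm <- lbp_map(radiograph(m, 8), lbp_params(8, 2))
  expect_identical(lm$values[8, 8], 255)

  # exactly one sample (p = 0, due east) darker, rest equal -> code 1
  m2 <- matrix(100L, 15, 15); m2[8, 10] <- 50L
  lm2 <- lbp_map(radiograph(m2, 8), lbp_params(8, 2))
  expect_identical(lm2$values[8, 8], 1)
})

test_that("lbp codes are bounded and invariant to a constant offset", {
  set.seed(63)
  m <- matrix(sample(0:200, 30 * 30, TRUE), 30, 30)
  a <- lbp_map(radiograph(m, 8), lbp_params(8, 7.5))
  expect_true(all(a$values >= 0 & a$values <= 255))
  expect_identical(a$value_domain, "label")
  b <- lbp_map(radiograph(m + 50L, 8), lbp_params(8, 7.5))
  expect_identical(a$values, b$values)
})
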