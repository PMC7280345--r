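test_that("phantom is deterministic and regions are where they claim", {
  sp <- phantom_spec(width = 96, height = 96, lesion_center = c(42, 48),
                     lesion_axes = c(10, 8), seed = 17)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$lesion_mask, b$lesion_mask)
  rm_ <- a$region_masks
  expect_true(all(rm_$background + rm_$dentin + rm_$enamel == 1))
  expect_true(all(a$lesion_mask[rm_$background] == FALSE))
  # mask areas close to the analytic ellipse areas
  expect_lt(abs(sum(a$lesion_mask) - pi * 10 * 8), 0.1 * pi * 10 * 8)
  tooth_area <- pi * (0.32 * 96) * (0.26 * 96)
  expect_lt(abs(sum(!rm_$background) - tooth_area), 0.05 * tooth_area)
})

test_that("noiseless phantom renders exact region means", {
  sp <- phantom_spec(width = 96, height = 96, lesion_center = c(42, 48),
                     lesion_axes = c(10, 8), noise_sigma = 0, mottle_sd = 0,
                     gradient = FALSE)
  ph <- generate_phantom(sp)
  px <- ph$image$pixels
  expect_true(all(px[ph$region_masks$enamel] == 3700))
  out_lesion_dentin <- ph$region_masks$dentin & !ph$lesion_mask
  expect_true(all(px[out_lesion_dentin] == 3000))
  expect_true(all(px[ph$lesion_mask] == round(3000 * 0.85)))
})

test_that("a lesion outside the tooth is rejected", {
  sp <- phantom_spec(width = 96, height = 96, lesion_center = c(10, 10),
                     lesion_axes = c(8, 8))
  expect_error(generate_phantom(sp), "outside the tooth")
})

test_that("enhancement_ratio contracts: zero, disjointness, degenerate sd", {
  m1 <- matrix(FALSE, 10, 10); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[7:9, 7:9] <- TRUE
  same <- matrix(5, 10, 10)
  expect_error(enhancement_ratio(same, m1, m2), "zero")
  set.seed(19)
  noisy <- matrix(rnorm(100), 10, 10)
  expect_identical(enhancement_ratio(noisy, m1, m1 | m2) |> suppressWarnings()
                   |> tryCatch(error = function(e) "disjoint"), "disjoint")
  # identical distributions -> small ratio; shifted -> large
  shifted <- noisy; shifted[m1] <- shifted[m1] + 100
  expect_gt(enhancement_ratio(shifted, m1, m2), 10)
  # noiseless phantom: raw image has zero pooled sd -> error path
  sp <- phantom_spec(width = 96, height = 96, lesion_center = c(42, 48),
                     lesion_axes = c(10, 8), noise_sigma = 0, mottle_sd = 0,
                     gradient = FALSE)
  ph <- generate_phantom(sp)
  expect_error(enhancement_ratio(ph$image, ph$region_masks$reference,
                                 ph$region_masks$enamel & FALSE), "non-empty")
})

test_that("null lesion is statistically invisible in the raw image", {
  ratios <- vapply(1:5, function(s) {
    ph <- generate_phantom(phantom_spec(seed = 200 + s, lesion_contrast = 0))
    enhancement_ratio(ph$image, ph$region_masks$lesion_core,
                      ph$region_masks$reference)
  }, numeric(1))
  expect_lt(stats::median(ratios), 0.5)
})
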