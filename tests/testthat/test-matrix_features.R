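# GLCM ---------------------------------------------------------------

test_that("glcm reproduces the hand-enumerated checkerboard and constant", {
  # [[0,1],[0,1]] in row-major reading
  cb <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  P <- glcm(cb, levels = 2)$probs
  expect_equal(P * 12, matrix(c(2, 4, 4, 2), 2, 2))
  expect_equal(sum(P), 1, tolerance = 1e-12)

  cst <- glcm(matrix(3L, 5, 5), levels = 32)$probs
  expect_identical(cst[4, 4], 1)
  expect_identical(sum(cst != 0), 1L)
})

test_that("glcm matrix matches pair-enumeration oracle and is symmetric", {
  set.seed(51)
  for (i in 1:20) {
    w <- matrix(sample(0:31, 121, TRUE), 11, 11)
    P <- glcm(w, 32)$probs
    expect_identical(P, t(P))
    expect_equal(P, oracle_glcm(w, 32), tolerance = 1e-12)
  }
})

test_that("the 14 haralick features match the literal-formula oracle", {
  set.seed(52)
  worst <- 0
  for (i in 1:60) {
    w <- matrix(sample(0:31, 441, TRUE), 21, 21)
    M <- glcm(w, 32)
    got <- glcm_features(M)
    want <- oracle_haralick(M$probs)
    worst <- max(worst, max(abs(got - want) / pmax(1, abs(want))))
  }
  expect_lt(worst, 1e-9)
})

test_that("haralick degenerate conventions on a constant window", {
  f <- glcm_features(glcm(matrix(7L, 21, 21), 32))
  expect_identical(unname(f["F1"]), 1)
  expect_identical(unname(f["F2"]), 0)
  expect_identical(unname(f["F9"]), 0)
  expect_identical(unname(f["F3"]), 0)   # zero marginal sd
  expect_identical(unname(f["F14"]), 0)  # degenerate Q
  # checkerboard contrast = 8/12
  expect_equal(unname(glcm_features(glcm(matrix(c(0L, 0L, 1L, 1L), 2, 2),
                                         2))["F2"]),
               2 / 3, tolerance = 1e-12)
})

test_that("glcm features are invariant under window rotation", {
  set.seed(53)
  w <- matrix(sample(0:31, 169, TRUE), 13, 13)
  rot <- t(w)[, 13:1]  # 90-degree rotation
  expect_equal(glcm_features(glcm(w, 32)), glcm_features(glcm(rot, 32)),
               tolerance = 1e-9)
})

# GTDM ---------------------------------------------------------------

test_that("gtdm single-spike and constant windows", {
  V <- gtdm(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3), K = 1)
  expect_identical(V$s[10], 9)
  expect_identical(V$p[10], 1)
  expect_identical(V$n_interior, 1L)

  Vc <- gtdm(matrix(4L, 9, 9), K = 1)
  expect_true(all(Vc$s == 0))

  expect_error(gtdm(matrix(0L, 3, 3), K = 2), "exceed")
})

test_that("gtdm vector and features match their oracles", {
  set.seed(54)
  worst <- 0
  for (i in 1:100) {
    w <- matrix(sample(0:255, 121, TRUE), 11, 11)
    V <- gtdm(w, K = 1)
    want <- oracle_gtdm(w, 1, 256)
    expect_identical(V$s, want$s)
    expect_identical(V$p, want$p)
    got <- gtdm_features(V)
    wantf <- oracle_gtdm_features(want$s, want$p, want$n_interior)
    worst <- max(worst, max(abs(got - wantf) / pmax(1, abs(wantf))))
  }
  expect_lt(worst, 1e-9)
})

test_that("gtdm degenerate conventions and the spike coarseness value", {
  fc <- gtdm_features(gtdm(matrix(4L, 9, 9), K = 1))
  expect_identical(unname(fc["F1"]), 1e12)  # capped sentinel 1/eps
  expect_identical(unname(fc["F3"]), 0)
  V <- gtdm(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3), K = 1)
  expect_equal(unname(gtdm_features(V)["F1"]), 1 / (1e-12 + 9),
               tolerance = 1e-12)
})

# RLM ----------------------------------------------------------------

test_that("rlm hand examples: 1x5 row, capped constant, stripes", {
  r <- rlm(matrix(c(3L, 3L, 3L, 0L, 0L), 1, 5), levels = 4, directions = "0")
  expect_identical(r$counts[4, 3], 1)  # run of 3s, length 3
  expect_identical(r$counts[1, 2], 1)  # run of 0s, length 2
  expect_identical(sum(r$counts), 2)
  f <- rlm_features(r)
  expect_equal(unname(f["F1"]), (1 / 9 + 1 / 4) / 2, tolerance = 1e-12)
  expect_equal(unname(f["F5"]), 2 / 5, tolerance = 1e-12)

  # 21x21 constant: 21 capped runs per direction
  rc <- rlm(matrix(2L, 21, 21), levels = 32)
  expect_identical(rc$counts[3, 10], 42)
  expect_identical(sum(rc$counts), 42)

  # alternating stripes: every run has length 1 -> SRE = 1
  st <- matrix(rep(c(0L, 1L), length.out = 21 * 21), 21, 21)
  fs <- rlm_features(rlm(st, levels = 2))
  expect_identical(unname(fs["F1"]), 1)
})

test_that("rlm matrix and features match their oracles", {
  set.seed(55)
  worst <- 0
  for (i in 1:100) {
    w <- matrix(sample(0:7, 121, TRUE), 11, 11)
    M <- rlm(w, levels = 8)
    want <- oracle_rlm(w, 8)
    expect_identical(M$counts, want)
    got <- rlm_features(M)
    wantf <- oracle_rlm_features(want, 121, 2)
    worst <- max(worst, max(abs(got - wantf) / pmax(1, abs(wantf))))
  }
  expect_lt(worst, 1e-9)
})

test_that("rlm total run count matches the oracle on 500 random windows", {
  set.seed(56)
  for (i in 1:500) {
    side <- sample(c(5L, 7L, 9L), 1)
    w <- matrix(sample(0:3, side^2, TRUE), side, side)
    expect_identical(sum(rlm(w, levels = 4)$counts),
                     sum(oracle_rlm(w, 4)))
  }
})

# maps ---------------------------------------------------------------

test_that("matrix-operator maps: constant-image conventions, finite everywhere", {
  cimg <- radiograph(matrix(50L, 14, 14), 8)
  gm <- glcm_maps(cimg, window_spec(5))
  expect_true(all(gm[["GLCM-F1"]]$values == 1))
  rm_ <- rlm_maps(cimg, window_spec(5))
  # all runs capped long: long-run features dominate short-run ones
  expect_true(all(rm_[["RLM-F2"]]$values > rm_[["RLM-F1"]]$values))

  set.seed(57)
  img <- radiograph(matrix(sample(0:255, 18 * 18, TRUE), 18, 18), 8)
  allmaps <- c(glcm_maps(img, window_spec(7)),
               gtdm_maps(img, window_spec(7)),
               rlm_maps(img, window_spec(7)))
  expect_length(allmaps, 30L)
  for (m in allmaps) expect_true(all(is.finite(m$values)))
})
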