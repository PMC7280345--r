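# Independent brute-force oracles, coded literally from the defining
# formulas with explicit loops. They share nothing with the package
# implementations beyond the documented conventions.

reflect_index <- function(i, n) {
  # mirror with edge included: ... 2 1 | 1 2 ... n | n n-1 ...
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

oracle_fof <- function(w, eps = 1e-12) {
  v <- as.double(w)
  n <- length(v)
  mu <- 0
  for (x in v) mu <- mu + x
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    m2 <- m2 + (x - mu)^2; m3 <- m3 + (x - mu)^3; m4 <- m4 + (x - mu)^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  skew <- if (m2 > 0) m3 / sqrt(m2)^3 else 0
  kurt <- if (m2 > 0) m4 / sqrt(m2)^4 - 3 else 0
  G <- max(v) + 1
  H <- numeric(G)
  for (x in v) H[x + 1] <- H[x + 1] + 1 / n
  energy <- 0; entropy <- 0
  for (i in seq_len(G)) {
    energy <- energy + H[i]^2
    entropy <- entropy - H[i] * log(H[i] + eps)
  }
  c(F1 = mu, F2 = m2, F3 = skew, F4 = kurt, F5 = energy, F6 = entropy)
}

oracle_glcm <- function(w, G, d = 1L) {
  nr <- nrow(w); nc <- ncol(w)
  counts <- matrix(0, G, G)
  offsets <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  for (o in offsets) {
    for (y in seq_len(nr)) for (x in seq_len(nc)) {
      y2 <- y + o[1]; x2 <- x + o[2]
      if (y2 >= 1 && y2 <= nr && x2 >= 1 && x2 <= nc) {
        a <- w[y, x] + 1L; b <- w[y2, x2] + 1L
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_haralick <- function(P) {
  G <- nrow(P)
  px <- py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  lev <- 0:(G - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  pplus <- numeric(2 * G - 1); pminus <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    pplus[(i - 1) + (j - 1) + 1] <- pplus[(i - 1) + (j - 1) + 1] + P[i, j]
    pminus[abs(i - j) + 1] <- pminus[abs(i - j) + 1] + P[i, j]
  }
  lg <- function(p) if (p > 0) log(p) else 0
  f1 <- 0; f2 <- 0; f4 <- 0; f5 <- 0; f9 <- 0; cor_num <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f1 <- f1 + p^2
    f4 <- f4 + ((i - 1) - mux)^2 * p
    f5 <- f5 + p / (1 + ((i - 1) - (j - 1))^2)
    f9 <- f9 - p * lg(p)
    cor_num <- cor_num + (i - 1) * (j - 1) * p
    if (p > 0) hxy1 <- hxy1 - p * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  f3 <- if (sdx > 0 && sdy > 0) (cor_num - mux * muy) / (sdx * sdy) else 0
  f6 <- 0; f8 <- 0
  for (k in seq_along(pplus)) {
    f6 <- f6 + (k - 1) * pplus[k]
    f8 <- f8 - pplus[k] * lg(pplus[k])
  }
  f7 <- 0
  for (k in seq_along(pplus)) f7 <- f7 + ((k - 1) - f6)^2 * pplus[k]
  f2 <- 0; f11 <- 0; mu_d <- 0
  for (nn in seq_along(pminus)) {
    f2 <- f2 + (nn - 1)^2 * pminus[nn]
    f11 <- f11 - pminus[nn] * lg(pminus[nn])
    mu_d <- mu_d + (nn - 1) * pminus[nn]
  }
  f10 <- 0
  for (nn in seq_along(pminus)) f10 <- f10 + ((nn - 1) - mu_d)^2 * pminus[nn]
  hx <- 0; hy <- 0
  for (i in 1:G) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  keep <- which(px > 0)
  f14 <- 0
  if (length(keep) >= 2) {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (kk in seq_along(keep)) {
        s <- s + P[keep[a], keep[kk]] * P[keep[b], keep[kk]] /
          (px[keep[a]] * py[keep[kk]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f14 <- sqrt(max(0, ev[2]))
  }
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5, F6 = f6, F7 = f7, F8 = f8,
    F9 = f9, F10 = f10, F11 = f11, F12 = f12, F13 = f13, F14 = f14)
}

oracle_gtdm <- function(w, K, G) {
  nr <- nrow(w); nc <- ncol(w)
  M <- (2 * K + 1)^2
  s <- numeric(G); cnt <- numeric(G); n_int <- 0
  for (y in (K + 1):(nr - K)) for (x in (K + 1):(nc - K)) {
    acc <- 0
    for (m in -K:K) for (n in -K:K) {
      if (m != 0 || n != 0) acc <- acc + w[y + m, x + n]
    }
    ibar <- acc / (M - 1)
    tone <- w[y, x]
    s[tone + 1] <- s[tone + 1] + abs(tone - ibar)
    cnt[tone + 1] <- cnt[tone + 1] + 1
    n_int <- n_int + 1
  }
  list(s = s, p = cnt / n_int, n_interior = n_int)
}

oracle_gtdm_features <- function(s, p, n_int, eps = 1e-12) {
  pres <- which(p > 0)
  Ng <- length(pres)
  ps <- 0
  for (i in pres) ps <- ps + p[i] * s[i]
  f1 <- 1 / (eps + ps)
  f2 <- 0
  if (Ng > 1) {
    acc <- 0
    for (i in pres) for (j in pres) acc <- acc + p[i] * p[j] * ((i - 1) - (j - 1))^2
    f2 <- acc / (Ng * (Ng - 1)) * sum(s) / n_int
  }
  den <- 0
  for (i in pres) for (j in pres) den <- den + abs((i - 1) * p[i] - (j - 1) * p[j])
  f3 <- if (den > 0) ps / den else 0
  f4 <- 0
  for (i in pres) for (j in pres) {
    f4 <- f4 + abs((i - 1) - (j - 1)) * (p[i] * s[i] + p[j] * s[j]) /
      (n_int * (p[i] + p[j]))
  }
  f5num <- 0
  for (i in pres) for (j in pres) f5num <- f5num + (p[i] + p[j]) * ((i - 1) - (j - 1))^2
  f5 <- f5num / (eps + sum(s))
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5)
}

oracle_rlm <- function(w, G, cap = 10L, directions = c("0", "90")) {
  counts <- matrix(0, G, cap)
  add_runs <- function(v) {
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      len <- min(j - i + 1L, cap)
      counts[v[i] + 1L, len] <<- counts[v[i] + 1L, len] + 1
      i <- j + 1L
    }
  }
  if ("0" %in% directions) for (r in seq_len(nrow(w))) add_runs(w[r, ])
  if ("90" %in% directions) for (cc in seq_len(ncol(w))) add_runs(w[, cc])
  counts
}

oracle_rlm_features <- function(counts, n_pixels, n_directions) {
  G <- nrow(counts); cap <- ncol(counts)
  nr <- sum(counts)
  f <- numeric(11)
  for (i in 1:G) for (j in 1:cap) {
    r <- counts[i, j]
    if (r == 0) next
    f[1] <- f[1] + r / j^2
    f[2] <- f[2] + r * j^2
    f[6] <- f[6] + r / i^2
    f[7] <- f[7] + r * i^2
    f[8] <- f[8] + r / (i^2 * j^2)
    f[9] <- f[9] + r * i^2 / j^2
    f[10] <- f[10] + r * j^2 / i^2
    f[11] <- f[11] + r * j^2 * i^2
  }
  for (i in 1:G) f[3] <- f[3] + sum(counts[i, ])^2
  for (j in 1:cap) f[4] <- f[4] + sum(counts[, j])^2
  out <- f / nr
  out[5] <- nr / (n_directions * n_pixels)
  names(out) <- paste0("F", 1:11)
  out
}

oracle_sda <- function(m, radius, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    cnt <- 0L
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy == 0 && dx == 0) next
      if (dy * dy + dx * dx > radius * radius) next
      yy <- reflect_index(y + dy, nr); xx <- reflect_index(x + dx, nc)
      if (m[yy, xx] >= m[y, x] + threshold) cnt <- cnt + 1L
    }
    out[y, x] <- cnt
  }
  out
}

# direct convolution + window mean of |response|, loops only (small inputs)
oracle_laws_energy <- function(m, kern_a, kern_b, side) {
  nr <- nrow(m); nc <- ncol(m)
  resp <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (i in 1:5) for (j in 1:5) {
      yy <- reflect_index(y + i - 3L, nr); xx <- reflect_index(x + j - 3L, nc)
      acc <- acc + kern_a[i] * kern_b[j] * m[yy, xx]
    }
    resp[y, x] <- abs(acc)
  }
  k <- (side - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (dy in -k:k) for (dx in -k:k) {
      acc <- acc + resp[reflect_index(y + dy, nr), reflect_index(x + dx, nc)]
    }
    out[y, x] <- acc / side^2
  }
  out
}

# smooth synthetic 12-bit images (sums of low-frequency waves plus gentle
# noise), used for the equalization/bit-cut commutation checks. The
# intensity marginal is blended towards flat (as in flat-field-corrected
# detector data): equalization/bit-cut order independence requires that
# no coarse histogram bin carry a large pixel mass.
smooth_image_12bit <- function(n = 64L, seed = 1L) {
  set.seed(seed)
  y <- matrix(seq_len(n), n, n) / n
  x <- matrix(rep(seq_len(n), each = n), n, n) / n
  f <- matrix(0, n, n)
  for (h in 1:4) {
    f <- f + stats::rnorm(1) * sin(2 * pi * (stats::runif(1) * 2 * x +
                                             stats::runif(1) * 2 * y +
                                             stats::runif(1)))
  }
  f <- f + 0.05 * matrix(stats::rnorm(n * n), n, n)
  u_raw <- (f - min(f)) / (max(f) - min(f))
  u_rank <- (rank(f, ties.method = "first") - 1) / (length(f) - 1)
  u <- 0.8 * matrix(u_rank, n, n) + 0.2 * u_raw
  radiograph(matrix(round(u * 4095), n, n), 12L)
}

random_window_8bit <- function(side = 21L, seed = 1L, levels = 256L) {
  set.seed(seed)
  matrix(sample(0:(levels - 1L), side * side, replace = TRUE), side, side)
}

expect_close <- function(actual, expected, tol = 1e-9) {
  testthat::expect_lt(max(abs(actual - expected) / pmax(1, abs(expected))), tol)
}
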