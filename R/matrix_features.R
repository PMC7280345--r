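# Matrix-based texture operators: gray level co-occurrence (GLCM, 14
# Haralick features), gray tone difference (GTDM, 5 Amadasun-King
# features) and run-length (RLM, 11 features). Each is defined on a single
# window; *_maps() wrappers run them over the moving window.

EPS_GUARD <- 1e-12

plogp <- function(p) {
  # natural log with the 0*log(0) := 0 convention
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

#' Gray level co-occurrence matrix of a window
#'
#' Counts ordered pairs of quantized levels at distance `d` along the four
#' angles 0, 45, 90 and 135 degrees, in both directions per angle (so the
#' matrix is symmetric), sums the four angle matrices and normalizes to
#' probabilities. Summing the angles removes the influence of texture
#' rotation.
#'
#' @param window_q integer matrix of quantized levels in `[0, levels - 1]`
#'   (see [quantize_levels()]).
#' @param levels number of quantized levels `G` (default 32).
#' @param d pixel distance between the paired pixels (default 1).
#' @return object of class `glcm_matrix`: list with `probs` (`G x G`,
#'   summing to 1), `levels`, `d`.
#' @export
glcm <- function(window_q, levels = 32L, d = 1L) {
  w <- pixel_matrix(as.matrix(window_q))
  if (max(w) >= levels) stop("window levels exceed `levels`")
  G <- as.integer(levels)
  nr <- nrow(w); nc <- ncol(w)
  counts <- matrix(0, G, G)
  # offsets (drow, dcol) for 0, 45, 90, 135 degrees
  offs <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- w[r1, c1, drop = FALSE]
    b <- w[r1 + dr, c1 + dc, drop = FALSE]
    tab <- tabulate(as.vector(a) * G + as.vector(b) + 1L, nbins = G * G)
    mo <- matrix(tab, G, G, byrow = TRUE)
    counts <- counts + mo + t(mo)   # both directions per angle
  }
  tot <- sum(counts)
  if (tot == 0) stop("window too small for distance ", d)
  structure(list(probs = counts / tot, levels = G, d = d),
            class = "glcm_matrix")
}

#' The fourteen Haralick features of a co-occurrence matrix
#'
#' Computes, from the normalized symmetric matrix `p(i, j)` with 0-based
#' levels `i, j` in `[0, G - 1]`:
#' F1 angular second moment (energy), F2 contrast, F3 correlation,
#' F4 variance (sum of squares about the marginal mean), F5 inverse
#' difference moment (homogeneity), F6 sum average, F7 sum variance
#' (about the sum average), F8 sum entropy, F9 entropy, F10 difference
#' variance, F11 difference entropy, F12/F13 the two information measures
#' of correlation, F14 the maximal correlation coefficient (square root of
#' the second-largest eigenvalue magnitude of the Q matrix).
#'
#' All logarithms are natural with `0 * log 0 := 0`. Sum-indexed features
#' use `k = i + j` in `[0, 2G - 2]` and difference-indexed features
#' `n = |i - j|` in `[0, G - 1]`. Degenerate conventions: correlation is 0
#' when a marginal standard deviation vanishes; F12 is 0 when both marginal
#' entropies vanish; F14 is 0 when the Q matrix has fewer than two
#' non-empty levels.
#'
#' @param M a `glcm_matrix` from [glcm()].
#' @return named numeric vector `F1`..`F14`.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "glcm_matrix"))
  P <- M$probs
  G <- M$levels
  lev <- 0:(G - 1)
  I <- matrix(lev, G, G)          # row level index
  J <- matrix(lev, G, G, byrow = TRUE)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  sdy <- sqrt(sum((lev - muy)^2 * py))

  # p_{x+y}(k), k = 0..2G-2 and p_{x-y}(n), n = 0..G-1
  pplus <- numeric(2 * G - 1)
  agg <- rowsum(as.vector(P), group = as.vector(I + J))
  pplus[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  pminus <- numeric(G)
  agg <- rowsum(as.vector(P), group = as.vector(abs(I - J)))
  pminus[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  kplus <- 0:(2 * G - 2)
  nminus <- lev

  f1 <- sum(P^2)
  f2 <- sum(nminus^2 * pminus)
  f3 <- if (sdx > 0 && sdy > 0) (sum(I * J * P) - mux * muy) / (sdx * sdy) else 0
  f4 <- sum((I - mux)^2 * P)
  f5 <- sum(P / (1 + (I - J)^2))
  f6 <- sum(kplus * pplus)
  f7 <- sum((kplus - f6)^2 * pplus)
  f8 <- -sum(plogp(pplus))
  f9 <- -sum(plogp(P))
  mu_d <- sum(nminus * pminus)
  f10 <- sum((nminus - mu_d)^2 * pminus)
  f11 <- -sum(plogp(pminus))

  pxy <- outer(px, py)
  hxy1 <- -sum(P[pxy > 0] * log(pxy[pxy > 0]))
  hxy2 <- -sum(plogp(pxy))
  hx <- -sum(plogp(px))
  hy <- -sum(plogp(py))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - f9))
  f13 <- sqrt(max(0, arg))

  keep <- which(px > 0)
  if (length(keep) >= 2L) {
    Ps <- P[keep, keep, drop = FALSE]
    A <- Ps / px[keep]                       # rows scaled by p_x(i)
    C <- sweep(Ps, 2L, py[keep], "/")        # cols scaled by p_y(k)
    Q <- A %*% t(C)
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f14 <- sqrt(max(0, ev[2]))
  } else {
    f14 <- 0
  }
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5, F6 = f6, F7 = f7,
    F8 = f8, F9 = f9, F10 = f10, F11 = f11, F12 = f12, F13 = f13, F14 = f14)
}

#' Gray tone difference vector of a window
#'
#' For every interior pixel (those whose full `(2K+1) x (2K+1)`
#' neighbourhood lies inside the window), the neighbourhood mean excluding
#' the centre is `Ibar = (box sum - centre) / (M - 1)` with
#' `M = (2K+1)^2`. The entry `s[i]` accumulates `|i - Ibar|` over interior
#' pixels of tone `i` (entries of absent tones are zero), and `p[i]` is the
#' fraction of interior pixels with tone `i`.
#'
#' @param window integer matrix of gray values in `[0, levels - 1]`.
#' @param K neighbourhood radius (default 1, i.e. 3 x 3); the window side
#'   must exceed `2 K`.
#' @param levels number of representable tones (default 256 — the
#'   operator runs on the 8-bit values directly, unquantized).
#' @return object of class `gtdm_vector`: list with `s`, `p` (length
#'   `levels`), `n_interior`, `levels`, `K`.
#' @export
gtdm <- function(window, K = 1L, levels = 256L) {
  w <- pixel_matrix(as.matrix(window))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  nr <- nrow(w); nc <- ncol(w)
  if (nr <= 2L * K || nc <= 2L * K) {
    stop("window side must exceed 2K = ", 2L * K)
  }
  if (max(w) >= levels) stop("window tones exceed `levels`")
  M <- (2L * K + 1L)^2
  ri <- (K + 1L):(nr - K)
  ci <- (K + 1L):(nc - K)
  # box sums over the (2K+1)^2 neighbourhood of each interior pixel
  box <- matrix(0, length(ri), length(ci))
  for (dr in -K:K) for (dc in -K:K) {
    box <- box + w[ri + dr, ci + dc, drop = FALSE]
  }
  centre <- w[ri, ci, drop = FALSE]
  ibar <- (box - centre) / (M - 1)
  tone <- as.vector(centre)
  dev <- abs(tone - as.vector(ibar))
  s <- numeric(levels)
  agg <- rowsum(dev, group = tone)
  s[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  p <- tabulate(tone + 1L, nbins = levels) / length(tone)
  structure(list(s = s, p = p, n_interior = length(tone),
                 levels = levels, K = K),
            class = "gtdm_vector")
}

#' The five gray-tone-difference features
#'
#' Amadasun-King statistics over present tones `i` (those with `p[i] > 0`),
#' with `N` the interior pixel count, `Ng` the number of present tones and
#' `eps = 1e-12` guarding reciprocals:
#' F1 coarseness `1 / (eps + sum p_i s_i)` (a constant window gives the
#' capped sentinel `1/eps`); F2 contrast
#' `[sum p_i p_j (i-j)^2 / (Ng (Ng-1))] * [sum s_i / N]`; F3 busyness
#' `sum p_i s_i / sum |i p_i - j p_j|`; F4 complexity
#' `sum |i-j| (p_i s_i + p_j s_j) / (N (p_i + p_j))`; F5 strength
#' `sum (p_i + p_j)(i-j)^2 / (eps + sum s_i)`. Any feature other than
#' coarseness whose denominator is zero returns 0.
#'
#' @param V a `gtdm_vector` from [gtdm()].
#' @return named numeric vector `F1`..`F5`.
#' @export
gtdm_features <- function(V) {
  stopifnot(inherits(V, "gtdm_vector"))
  pres <- which(V$p > 0)
  i <- pres - 1                       # 0-based tones
  p <- V$p[pres]
  s <- V$s[pres]
  N <- V$n_interior
  Ng <- length(pres)
  ps <- sum(p * s)

  f1 <- 1 / (EPS_GUARD + ps)

  dij2 <- outer(i, i, function(a, b) (a - b)^2)
  f2 <- if (Ng > 1) (sum(outer(p, p) * dij2) / (Ng * (Ng - 1))) * (sum(s) / N) else 0

  den_busy <- sum(abs(outer(i * p, i * p, "-")))
  f3 <- if (den_busy > 0) ps / den_busy else 0

  absd <- sqrt(dij2)
  psum <- outer(p, p, "+")
  f4 <- sum(absd * (outer(p * s, p * s, "+")) / (N * psum))

  f5 <- sum(psum * dij2) / (EPS_GUARD + sum(s))

  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5)
}

#' Run-length matrix of a window
#'
#' Counts maximal runs of equal quantized level along every row (0
#' degrees) and/or every column (90 degrees); runs longer than `cap`
#' pixels fall into the capped length bin. The directional matrices are
#' summed before feature calculation to remove the influence of texture
#' rotation.
#'
#' @param window_q integer matrix of quantized levels in `[0, levels - 1]`.
#' @param levels number of quantized levels (default 32).
#' @param cap maximum tabulated run length (default 10).
#' @param directions subset of `c("0", "90")` (default both).
#' @return object of class `rlm_matrix`: list with `counts`
#'   (`levels x cap`), `levels`, `cap`, `n_pixels`, `n_directions`.
#' @export
rlm <- function(window_q, levels = 32L, cap = 10L,
                directions = c("0", "90")) {
  w <- pixel_matrix(as.matrix(window_q))
  if (max(w) >= levels) stop("window levels exceed `levels`")
  directions <- match.arg(directions, several.ok = TRUE)
  G <- as.integer(levels); cap <- as.integer(cap)
  counts <- matrix(0, G, cap)
  scan <- function(v) {
    r <- rle(v)
    len <- pmin(r$lengths, cap)
    for (t in seq_along(len)) {
      counts[r$values[t] + 1L, len[t]] <<- counts[r$values[t] + 1L, len[t]] + 1
    }
  }
  if ("0" %in% directions) for (r in seq_len(nrow(w))) scan(w[r, ])
  if ("90" %in% directions) for (cc in seq_len(ncol(w))) scan(w[, cc])
  structure(list(counts = counts, levels = G, cap = cap,
                 n_pixels = length(w), n_directions = length(directions)),
            class = "rlm_matrix")
}

#' The eleven run-length features
#'
#' With run counts `r(i, j)` (0-based level `i`, run-length bin `j` in
#' `1..cap`), total run count `nr` and gray-level weight `i + 1` (so the
#' low-gray-level emphases stay finite at level 0):
#' F1 short run emphasis, F2 long run emphasis, F3 gray level
#' nonuniformity, F4 run-length nonuniformity, F5 run percentage
#' (`nr` divided by the window pixel count times the number of scan
#' directions), F6 low / F7 high gray level run emphasis, F8-F11 the four
#' joint short/long-run low/high-gray-level emphases.
#'
#' @param M an `rlm_matrix` from [rlm()].
#' @return named numeric vector `F1`..`F11`.
#' @export
rlm_features <- function(M) {
  stopifnot(inherits(M, "rlm_matrix"))
  r <- M$counts
  nr <- sum(r)
  if (nr == 0) stop("empty run-length matrix")
  gl <- (seq_len(M$levels))          # i + 1 weight, i 0-based
  jl <- seq_len(M$cap)
  Gw <- matrix(gl, M$levels, M$cap)
  Jw <- matrix(jl, M$levels, M$cap, byrow = TRUE)
  c(F1 = sum(r / Jw^2) / nr,
    F2 = sum(r * Jw^2) / nr,
    F3 = sum(rowSums(r)^2) / nr,
    F4 = sum(colSums(r)^2) / nr,
    F5 = nr / (M$n_directions * M$n_pixels),
    F6 = sum(r / Gw^2) / nr,
    F7 = sum(r * Gw^2) / nr,
    F8 = sum(r / (Gw^2 * Jw^2)) / nr,
    F9 = sum(r * Gw^2 / Jw^2) / nr,
    F10 = sum(r * Jw^2 / Gw^2) / nr,
    F11 = sum(r * Jw^2 * Gw^2) / nr)
}

#' Windowed matrix-operator feature maps
#'
#' Run the co-occurrence, gray-tone-difference or run-length features over
#' the moving window. GLCM and RLM operate on the image quantized globally
#' to `levels` gray levels (global bounds keep identical textures
#' comparable across the image); GTDM operates on the 8-bit preprocessed
#' values directly.
#'
#' @param image a `radiograph` (8-bit preprocessed).
#' @param spec a [window_spec()].
#' @param levels quantized levels for GLCM/RLM (default 32).
#' @param d GLCM pixel distance (default 1).
#' @param K GTDM neighbourhood radius (default 1).
#' @return named list of `feature_map`s (`GLCM-F1`..`F14`,
#'   `GTDM-F1`..`F5`, `RLM-F1`..`F11`).
#' @export
glcm_maps <- function(image, spec = window_spec(), levels = 32L, d = 1L) {
  q <- quantize_levels(image, levels)
  map_over_windows(q, function(w) glcm_features(glcm(w, levels, d)), spec,
                   feature_names = paste0("GLCM-F", 1:14),
                   provenance = list(operator = "GLCM", levels = levels, d = d))
}

#' @rdname glcm_maps
#' @export
gtdm_maps <- function(image, spec = window_spec(), K = 1L) {
  stopifnot(inherits(image, "radiograph"))
  G <- 2^image$bit_depth
  map_over_windows(image, function(w) gtdm_features(gtdm(w, K, levels = G)),
                   spec, feature_names = paste0("GTDM-F", 1:5),
                   provenance = list(operator = "GTDM", K = K))
}

#' @rdname glcm_maps
#' @export
rlm_maps <- function(image, spec = window_spec(), levels = 32L) {
  q <- quantize_levels(image, levels)
  map_over_windows(q, function(w) rlm_features(rlm(w, levels)), spec,
                   feature_names = paste0("RLM-F", 1:11),
                   provenance = list(operator = "RLM", levels = levels))
}
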