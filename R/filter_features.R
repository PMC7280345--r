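# Convolution-based texture operators: Laws' texture energy measures and
# local binary patterns.

#' Laws' 1-D kernels
#'
#' Level `L5 = (1,4,6,4,1)`, edge `E5 = (-1,-2,0,2,1)`, spot
#' `S5 = (-1,0,2,0,-1)` and ripple `R5 = (1,-4,6,-4,1)`. The 5 x 5 masks
#' are outer products of these; all but `L5` sum to zero, so every mask
#' containing an `E5`, `S5` or `R5` component has zero response on a
#' constant image.
#'
#' @return named list of the four integer vectors.
#' @export
laws_kernels <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1),
       R5 = c(1, -4, 6, -4, 1))
}

# Direct 2-D convolution (correlation with the flipped kernel is identical
# for these symmetric/antisymmetric products up to sign, which the energy
# step removes; we correlate) with mirror-reflect padding.
convolve2_reflect <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  rr <- (kr - 1L) %/% 2L; rc <- (kc - 1L) %/% 2L
  pm <- pad_reflect(m, max(rr, rc))
  off <- max(rr, rc)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    kv <- kernel[i, j]
    if (kv == 0) next
    dr <- i - 1L - rr; dc <- j - 1L - rc
    out <- out + kv * pm[(1L + off + dr):(H + off + dr),
                         (1L + off + dc):(W + off + dc), drop = FALSE]
  }
  out
}

# Exact moving-window box mean via a summed-area table on the
# reflect-padded matrix.
box_mean_reflect <- function(m, side) {
  k <- (side - 1L) %/% 2L
  pm <- pad_reflect(m, k)
  Hp <- nrow(pm); Wp <- ncol(pm)
  sat <- matrix(0, Hp + 1L, Wp + 1L)
  sat[-1L, -1L] <- t(apply(apply(pm, 2L, cumsum), 1L, cumsum))
  H <- nrow(m); W <- ncol(m)
  r2 <- (1L + side):(H + side); r1 <- 1:H
  c2 <- (1L + side):(W + side); c1 <- 1:W
  (sat[r2, c2, drop = FALSE] - sat[r1, c2, drop = FALSE] -
     sat[r2, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]) / side^2
}

#' Laws' texture energy maps
#'
#' Convolves the image with the sixteen 5 x 5 outer-product masks of the
#' four Laws kernels (mirror-reflect padding), takes the local energy as
#' the moving-window mean of the absolute response, averages each
#' transposed pair of masks (e.g. `E5L5` with `L5E5`) into one
#' orientation-pooled map, and drops the pure level mask `L5L5`, leaving
#' nine maps tagged `LAWS-F1`..`LAWS-F9` in lexicographic order of the
#' normalized pair name:
#' E5E5, E5L5, E5R5, E5S5, L5R5, L5S5, R5R5, R5S5, S5S5.
#'
#' @param image a `radiograph` (8-bit preprocessed).
#' @param spec a [window_spec()]; its side is the energy-averaging window.
#' @return named list of nine `feature_map`s.
#' @export
laws_maps <- function(image, spec = window_spec()) {
  if (!inherits(spec, "window_spec")) spec <- window_spec(spec)
  m <- pixel_matrix(image)
  kern <- laws_kernels()
  nms <- names(kern)
  energy <- list()
  for (a in nms) for (b in nms) {
    mask <- outer(kern[[a]], kern[[b]])   # a varies along rows
    energy[[paste0(a, b)]] <-
      box_mean_reflect(abs(convolve2_reflect(m, mask)), spec$side)
  }
  pairs <- t(utils::combn(sort(nms), 2))   # alphabetical within each pair
  pair_names <- c(apply(pairs, 1L, paste0, collapse = ""),
                  paste0(nms, nms))
  pair_names <- sort(setdiff(pair_names, "L5L5"))
  maps <- lapply(seq_along(pair_names), function(i) {
    nm <- pair_names[i]
    a <- substr(nm, 1L, 2L); b <- substr(nm, 3L, 4L)
    v <- if (a == b) energy[[nm]]
         else (energy[[paste0(a, b)]] + energy[[paste0(b, a)]]) / 2
    feature_map(v, provenance = list(operator = "LAWS", masks = nm,
                                     feature = paste0("LAWS-F", i),
                                     window = spec$side))
  })
  names(maps) <- paste0("LAWS-F", seq_along(pair_names))
  maps
}

#' Local binary pattern parameters
#'
#' @param P number of circularly sampled points (default 8).
#' @param R sampling radius in pixels (the radiograph study grid is
#'   `R = 5..20` at `P = 8`).
#' @return object of class `lbp_params`.
#' @export
lbp_params <- function(P = 8L, R = 5) {
  P <- as.integer(P)
  if (P < 4L) stop("P must be >= 4")
  if (!is.numeric(R) || R < 1) stop("R must be >= 1")
  structure(list(P = P, R = R), class = "lbp_params")
}

#' Local binary pattern map
#'
#' For every pixel, samples `P` points evenly spaced on the circle of
#' radius `R` (bilinear interpolation at non-integer coordinates,
#' mirror-reflect padding) and sets bit `p` when
#' `I(centre) - I(sample_p) > 0` (strictly positive difference). The
#' resulting code in `[0, 2^P - 1]` is a label, not a magnitude: the map
#' is `value_domain = "label"` and exempt from post-processing arithmetic.
#' Adding a constant to the image leaves the map unchanged.
#'
#' @param image a `radiograph` (8-bit preprocessed).
#' @param params an [lbp_params()].
#' @return a label-valued `feature_map` of integer codes.
#' @export
lbp_map <- function(image, params = lbp_params()) {
  stopifnot(inherits(params, "lbp_params"))
  m <- pixel_matrix(image)
  H <- nrow(m); W <- ncol(m)
  P <- params$P; R <- params$R
  pad <- as.integer(ceiling(R)) + 1L
  pm <- pad_reflect(m, pad)
  rows <- matrix(seq_len(H) + pad, H, W)
  cols <- matrix(rep(seq_len(W) + pad, each = H), H, W)
  centre <- m
  code <- matrix(0, H, W)
  for (p in 0:(P - 1L)) {
    ang <- 2 * pi * p / P
    # sample p=0 to the east, advancing counter-clockwise in image axes
    sr <- rows - R * sin(ang)
    sc <- cols + R * cos(ang)
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    idx <- function(r, cc) pm[cbind(as.vector(r), as.vector(cc))]
    samp <- (1 - fr) * (1 - fc) * idx(r0, c0) +
            (1 - fr) * fc       * idx(r0, c0 + 1) +
            fr       * (1 - fc) * idx(r0 + 1, c0) +
            fr       * fc       * idx(r0 + 1, c0 + 1)
    samp <- matrix(samp, H, W)
    # the 1e-9 guard absorbs bilinear-weight roundoff (the four weights
    # need not sum to exactly 1 in floating point); genuine differences
    # on integer images are never that small
    code <- code + 2^p * (centre - samp > 1e-9)
  }
  feature_map(code,
              provenance = list(operator = "LBP", P = P, R = R,
                                feature = sprintf("LBP-R%g", R)),
              value_domain = "label")
}
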