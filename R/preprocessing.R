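#' Bit-depth reduction
#'
#' Rescales intensities from the image's bit depth to `target_bits` by
#' `v' = round(v * (2^target - 1) / (2^source - 1))`, the usual monotone
#' full-range remap (0 stays 0, the source maximum becomes the target
#' maximum). Used to bring 12-bit detector data to the 8-bit range most
#' texture operators assume.
#'
#' @param image a `radiograph`.
#' @param target_bits target bit depth, `<=` the image's bit depth.
#' @return a `radiograph` at `target_bits`.
#' @export
bit_reduce <- function(image, target_bits = 8L) {
  stopifnot(inherits(image, "radiograph"))
  target_bits <- as.integer(target_bits)
  if (target_bits > image$bit_depth) {
    stop("target_bits (", target_bits, ") exceeds source bit depth (",
         image$bit_depth, ")")
  }
  if (target_bits == image$bit_depth) return(image)
  scale <- (2^target_bits - 1) / (2^image$bit_depth - 1)
  px <- round_half_up(image$pixels * scale)
  radiograph(px, target_bits, image$pixel_spacing_mm)
}

#' Histogram equalization
#'
#' Classical cumulative-distribution remap at the image's own bit depth:
#' `out(v) = round((cdf(v) - cdf_min) / (1 - cdf_min) * (2^bits - 1))`,
#' where `cdf_min` is the CDF at the lowest occupied level. The mapping is
#' monotone non-decreasing; a constant image (single occupied level, so the
#' denominator vanishes) maps to all zeros.
#'
#' @param image a `radiograph`.
#' @return a `radiograph` at the same bit depth.
#' @export
histogram_equalize <- function(image) {
  stopifnot(inherits(image, "radiograph"))
  G <- 2^image$bit_depth
  counts <- tabulate(as.vector(image$pixels) + 1L, nbins = G)
  cdf <- cumsum(counts) / sum(counts)
  cdf_min <- cdf[which(counts > 0L)[1L]]
  if (cdf_min >= 1) {  # single occupied level
    px <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
    return(radiograph(px, image$bit_depth, image$pixel_spacing_mm))
  }
  lut <- round_half_up((cdf - cdf_min) / (1 - cdf_min) * (G - 1))
  lut[lut < 0] <- 0
  px <- matrix(lut[as.vector(image$pixels) + 1L],
               nrow(image$pixels), ncol(image$pixels))
  radiograph(px, image$bit_depth, image$pixel_spacing_mm)
}

#' Statistical dominance algorithm parameters
#'
#' @param radius Euclidean disc radius in pixels (default 20).
#' @param threshold dominance threshold added to the centre intensity
#'   (default 0, making the count independent of absolute image quality).
#' @return object of class `sda_params`.
#' @export
sda_params <- function(radius = 20L, threshold = 0L) {
  radius <- as.integer(radius); threshold <- as.integer(threshold)
  if (radius < 1L) stop("SDA radius must be >= 1")
  if (threshold < 0L) stop("SDA threshold must be >= 0")
  structure(list(radius = radius, threshold = threshold), class = "sda_params")
}

# Integer offsets (m, n) != (0, 0) with m^2 + n^2 <= r^2.
sda_disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(m = -r:r, n = -r:r)
  g <- g[g$m^2 + g$n^2 <= radius^2 & !(g$m == 0 & g$n == 0), , drop = FALSE]
  g
}

#' Statistical dominance algorithm (SDA)
#'
#' For every pixel `c`, counts the pixels `p` in the Euclidean disc of
#' radius `radius` around `c` (centre excluded, borders mirror-reflected)
#' whose intensity satisfies `I(p) >= I(c) + threshold`: the number of
#' neighbours that dominate the centre. Raw counts lie between 0 and the
#' number of disc offsets (12 for radius 2, 1256 for the default radius 20).
#' The raw map is a local-rank transform that flattens global illumination
#' while keeping fine texture.
#'
#' @param image a `radiograph`.
#' @param params an [sda_params()].
#' @return a `feature_map` of raw dominance counts.
#' @seealso [scale_sda_to_8bit()] for the display scaling used by the
#'   preprocessing path.
#' @export
sda <- function(image, params = sda_params()) {
  stopifnot(inherits(image, "radiograph"), inherits(params, "sda_params"))
  m <- image$pixels
  r <- params$radius; t <- params$threshold
  pm <- pad_reflect(m, r)
  H <- nrow(m); W <- ncol(m)
  off <- sda_disc_offsets(r)
  counts <- matrix(0, H, W)
  thr <- m + t
  for (i in seq_len(nrow(off))) {
    dm <- off$m[i]; dn <- off$n[i]
    nb <- pm[(1L + r + dm):(H + r + dm), (1L + r + dn):(W + r + dn),
             drop = FALSE]
    counts <- counts + (nb >= thr)
  }
  feature_map(counts,
              provenance = list(preprocess = "sda", radius = r, threshold = t),
              value_domain = "real")
}

#' Scale a raw SDA map to 8 bits
#'
#' Linearly maps the raw dominance counts from `[min, max]` onto
#' `[0, 255]` with rounding; a constant raw map (degenerate range) scales
#' to all zeros.
#'
#' @param map a `feature_map` from [sda()].
#' @return an 8-bit `radiograph`.
#' @export
scale_sda_to_8bit <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    px <- matrix(0L, nrow(v), ncol(v))
  } else {
    px <- round_half_up((v - lo) / (hi - lo) * 255)
  }
  radiograph(px, 8L)
}
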