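# Display post-processing: turn a real-valued feature map into an 8-bit
# image. All three transforms are monotone non-decreasing in the map
# values; label-valued maps (LBP codes, CLU/QNT renderings) should only
# ever pass through the plain min-max normalization.

check_finite_map <- function(map) {
  v <- pixel_matrix(map)
  if (any(!is.finite(v))) stop("feature map contains NaN/Inf; refusing to scale")
  v
}

post_provenance <- function(map, name) {
  prov <- if (inherits(map, "feature_map")) map$provenance else list()
  prov$postprocess <- name
  prov
}

#' Min-max 8-bit normalization
#'
#' Maps `[min, max]` of the map linearly onto `[0, 255]` with rounding;
#' a constant map has no range and becomes all zeros.
#'
#' @param map a `feature_map` (or matrix) with finite values.
#' @return an 8-bit `radiograph`.
#' @export
normalize_8bit <- function(map) {
  v <- check_finite_map(map)
  lo <- min(v); hi <- max(v)
  px <- if (hi == lo) matrix(0L, nrow(v), ncol(v))
        else round_half_up((v - lo) / (hi - lo) * 255)
  radiograph(px, 8L)
}

#' Histogram stretching (HSTR)
#'
#' Percentile-clipped contrast stretch: values are clipped at the 0.5th
#' and 99.5th percentiles of the map and the clipped range mapped linearly
#' onto `[0, 255]`. Extreme outliers saturate instead of compressing the
#' dynamic range of everything else, which is the point of stretching
#' after plain 8-bit normalization.
#'
#' @param map a `feature_map` (or matrix) with finite values.
#' @param clip_percentiles lower/upper clip probabilities
#'   (default `c(0.005, 0.995)`).
#' @return an 8-bit `radiograph`.
#' @export
hstr <- function(map, clip_percentiles = c(0.005, 0.995)) {
  v <- check_finite_map(map)
  q <- stats::quantile(v, probs = clip_percentiles, names = FALSE)
  if (q[2] <= q[1]) {
    px <- matrix(0L, nrow(v), ncol(v))
  } else {
    s <- pmin(pmax(v, q[1]), q[2])
    px <- round_half_up((s - q[1]) / (q[2] - q[1]) * 255)
  }
  radiograph(px, 8L)
}

#' Rank-based histogram equalization of a real-valued map
#'
#' Real-valued maps have no natural binning, so equalization is done by
#' rank: values are replaced by their average ranks (ties share the mean
#' rank) and the rank range scaled onto `[0, 255]`. For maps whose values
#' are all distinct the output histogram is exactly uniform; ties bound
#' the deviation from uniformity by the largest tie mass.
#'
#' @param map a `feature_map` (or matrix) with finite values.
#' @return an 8-bit `radiograph`.
#' @export
heq_post <- function(map) {
  v <- check_finite_map(map)
  r <- rank(as.vector(v), ties.method = "average")
  lo <- min(r); hi <- max(r)
  px <- if (hi == lo) matrix(0L, nrow(v), ncol(v))
        else matrix(round_half_up((r - lo) / (hi - lo) * 255), nrow(v), ncol(v))
  radiograph(px, 8L)
}
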