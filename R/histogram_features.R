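#' Normalized window histogram
#'
#' `probs[i + 1] = count(v == i) / n` for gray level `i` in `[0, levels - 1]`;
#' the probabilities sum to one.
#'
#' @param window integer matrix (or vector) of gray values.
#' @param levels number of representable levels `G` (default 256 for 8-bit
#'   windows); all window values must be `< levels`.
#' @return numeric vector of length `levels`.
#' @export
window_histogram <- function(window, levels = 256L) {
  v <- as.vector(pixel_matrix(as.matrix(window)))
  if (max(v) >= levels) stop("window values exceed the histogram range")
  tabulate(v + 1L, nbins = levels) / length(v)
}

# epsilon guarding log(0) in the entropy sum; "relatively small".
FOF_EPS <- 1e-12

#' First-order features of a window
#'
#' The six histogram statistics of the window's intensity distribution,
#' using population moments (1/n normalization):
#' \describe{
#'   \item{F1 mean}{arithmetic mean of the window.}
#'   \item{F2 variance}{second central moment.}
#'   \item{F3 skewness}{third central moment times `sd^-3`.}
#'   \item{F4 kurtosis}{fourth central moment times `sd^-4`, minus 3
#'     (excess kurtosis).}
#'   \item{F5 energy}{`sum(H(i)^2)` over the normalized histogram; 1 for a
#'     constant window, `1/n` when all values differ.}
#'   \item{F6 entropy}{`-sum(H(i) * log(H(i) + eps))` in nats,
#'     `eps = 1e-12`; absent levels contribute nothing.}
#' }
#' When the variance is zero, skewness and kurtosis are 0 by convention.
#'
#' @param window integer matrix or vector of gray values at their native
#'   bit depth (no quantization is applied for first-order features).
#' @return named numeric vector `F1`..`F6`.
#' @export
fof <- function(window) {
  v <- as.double(as.vector(as.matrix(window)))
  n <- length(v)
  mu <- sum(v) / n
  d <- v - mu
  m2 <- sum(d^2) / n
  if (m2 > 0) {
    s <- sqrt(m2)
    skew <- (sum(d^3) / n) / s^3
    kurt <- (sum(d^4) / n) / s^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  p <- tabulate(match(v, unique(v)), nbins = length(unique(v))) / n
  energy <- sum(p^2)
  entropy <- -sum(p * log(p + FOF_EPS))
  c(F1 = mu, F2 = m2, F3 = skew, F4 = kurt, F5 = energy, F6 = entropy)
}

#' First-order feature maps
#'
#' Applies [fof()] over the moving window, yielding the six maps
#' `FOF-F1` (mean) through `FOF-F6` (entropy). The energy map `FOF-F5` is
#' the one that renders cavities as a pseudo-three-dimensional relief on
#' radiographs; `FOF-F6` outlines lesions as bright consistent areas.
#'
#' @param image a `radiograph` (normally 8-bit preprocessed).
#' @param spec a [window_spec()].
#' @return named list of six `feature_map`s.
#' @export
fof_maps <- function(image, spec = window_spec()) {
  map_over_windows(image, fof, spec,
                   feature_names = paste0("FOF-F", 1:6),
                   provenance = list(operator = "FOF"))
}
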