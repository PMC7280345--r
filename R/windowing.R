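#' Moving-window specification
#'
#' The moving window is square with an odd side so that it can be centred on
#' the pixel of interest; borders are completed by mirror reflection. The
#' default side of 21 pixels keeps the window reasonably smaller than the
#' image while giving each statistic 441 samples.
#'
#' @param side odd integer >= 3, window side in pixels.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(side = 21L) {
  side <- as.integer(side)
  if (is.na(side) || side < 3L) stop("window side must be an integer >= 3")
  if (side %% 2L == 0L) stop("window side must be odd (got ", side, ")")
  structure(list(side = side, padding = "reflect"), class = "window_spec")
}

# Mirror-reflect padding (edge row/column included in the mirror image):
# c(k:1, 1:n, n:(n-k+1)) index trick on each axis. Requires k <= dim.
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k > nr || k > nc) stop("reflection pad ", k, " exceeds image size")
  ri <- c(k:1, 1:nr, nr:(nr - k + 1L))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1L))
  m[ri, ci, drop = FALSE]
}

#' Turn a per-window statistic into per-pixel feature maps
#'
#' Centres a `side x side` window on every pixel (mirror-reflected at the
#' borders), applies `statistic` to the raw window contents and collects the
#' results into one feature map per returned component. This brute-force
#' engine is the normative definition of every windowed operator in the
#' package; faster specialised routes must agree with it.
#'
#' @param image a `radiograph`, `feature_map` or matrix.
#' @param statistic function taking a `side x side` matrix, returning a
#'   scalar or a fixed-length (preferably named) numeric vector.
#' @param spec a [window_spec()].
#' @param feature_names optional character vector naming the components of a
#'   vector-valued statistic.
#' @param value_domain passed to [feature_map()].
#' @param provenance base provenance list copied into every output map.
#' @return a single `feature_map`, or a named list of them for vector-valued
#'   statistics.
#' @export
map_over_windows <- function(image, statistic, spec = window_spec(),
                             feature_names = NULL, value_domain = "real",
                             provenance = list()) {
  if (!inherits(spec, "window_spec")) spec <- window_spec(spec)
  m <- pixel_matrix(image)
  side <- spec$side
  k <- (side - 1L) %/% 2L
  pm <- pad_reflect(m, k)
  H <- nrow(m); W <- ncol(m)

  first <- statistic(pm[1:side, 1:side, drop = FALSE])
  nf <- length(first)
  if (is.null(feature_names)) {
    feature_names <- names(first)
    if (is.null(feature_names) && nf > 1L) {
      feature_names <- paste0("stat", seq_len(nf))
    }
  }
  out <- matrix(NA_real_, nf, H * W)
  idx <- 1L
  for (x in 1:W) {
    cols <- x:(x + side - 1L)
    for (y in 1:H) {
      w <- pm[y:(y + side - 1L), cols, drop = FALSE]
      out[, idx] <- statistic(w)
      idx <- idx + 1L
    }
  }
  if (any(!is.finite(out))) stop("statistic produced non-finite values")

  mk <- function(i, nm) {
    prov <- provenance
    prov$feature <- nm
    prov$window <- side
    feature_map(matrix(out[i, ], H, W), provenance = prov,
                value_domain = value_domain)
  }
  if (nf == 1L) return(mk(1L, if (is.null(feature_names)) NULL else feature_names[1L]))
  maps <- lapply(seq_len(nf), function(i) mk(i, feature_names[i]))
  names(maps) <- feature_names
  maps
}

#' Global gray-level quantization
#'
#' Maps intensities onto `levels` bins by
#' `floor((v - lo) / (hi - lo + 1) * levels)` where `lo`/`hi` default to the
#' minimum/maximum of the *full* image. The bounds are global on purpose:
#' two windows with identical raw content then quantize identically
#' wherever they sit, which keeps the co-occurrence and run-length maps
#' comparable across the image. A constant image maps to level 0 everywhere.
#'
#' @param image radiograph, feature_map or matrix (whole-number values).
#' @param levels number of gray levels (>= 2), default 32.
#' @param lo,from,hi optional explicit bounds (used when quantizing a window
#'   with the bounds of its parent image).
#' @return integer matrix of levels in `[0, levels - 1]`.
#' @export
quantize_levels <- function(image, levels = 32L, lo = NULL, hi = NULL) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("`levels` must be >= 2")
  m <- pixel_matrix(image)
  if (is.null(lo)) lo <- min(m)
  if (is.null(hi)) hi <- max(m)
  q <- floor((m - lo) / (hi - lo + 1) * levels)
  q[q < 0] <- 0
  q[q > levels - 1L] <- levels - 1L
  matrix(as.integer(q), nrow(m), ncol(m))
}
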