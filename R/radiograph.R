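#' Radiograph image container
#'
#' A `radiograph` wraps a rectangular grid of non-negative integer intensities
#' together with its declared bit depth (8, 12 or 16) and, when known, the
#' detector pixel spacing in millimetres. All operators in the package take
#' and return this container so that bit-depth bookkeeping is explicit:
#' every intensity must satisfy `0 <= v < 2^bit_depth`.
#'
#' Pixels are stored as an integer matrix with `nrow = height` and
#' `ncol = width`; `x[i, j]` is row (image line) `i`, column `j`.
#'
#' @param pixels integer (or whole-number numeric) matrix of intensities.
#' @param bit_depth one of 8, 12, 16.
#' @param pixel_spacing_mm optional positive scalar, detector pitch in mm.
#' @return an object of class `radiograph`.
#' @examples
#' img <- radiograph(matrix(0:15, 4, 4), bit_depth = 8)
#' img
#' @export
radiograph <- function(pixels, bit_depth, pixel_spacing_mm = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("`bit_depth` must be one of 8, 12, 16 (got ", bit_depth, ")")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  storage <- pixels
  if (is.double(storage)) {
    if (any(storage != round(storage), na.rm = TRUE)) {
      stop("pixel intensities must be whole numbers")
    }
    storage <- matrix(as.integer(round(storage)), nrow(pixels), ncol(pixels))
  }
  if (anyNA(storage)) stop("pixel intensities must not contain NA")
  if (min(storage) < 0L) stop("pixel intensities must be non-negative")
  if (max(storage) >= 2^bit_depth) {
    stop("intensity ", max(storage), " exceeds the ", bit_depth, "-bit range")
  }
  if (!is.null(pixel_spacing_mm)) {
    if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
        pixel_spacing_mm <= 0) {
      stop("`pixel_spacing_mm` must be a positive scalar")
    }
  }
  structure(
    list(pixels = storage, bit_depth = as.integer(bit_depth),
         pixel_spacing_mm = pixel_spacing_mm),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d, %d-bit, intensities [%d, %d]%s\n",
              ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels),
              if (is.null(x$pixel_spacing_mm)) ""
              else sprintf(", spacing %g mm", x$pixel_spacing_mm)))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' @export
as.matrix.radiograph <- function(x, ...) x$pixels

#' Feature map container
#'
#' A `feature_map` is the per-pixel result of running a texture statistic
#' over a moving window: a real-valued grid with the same spatial extent as
#' its source image, plus a provenance record (preprocessing, operator,
#' feature identifier, window and operator parameters, post-processing) that
#' fully determines the map given the input image and seed. Maps are either
#' `"real"`-valued (texture statistics, subject to display post-processing)
#' or `"label"`-valued (LBP codes, cluster/quantization renderings, which
#' post-processing arithmetic must not touch).
#'
#' @param values numeric matrix, no NaN/Inf.
#' @param provenance named list describing how the map was produced.
#' @param value_domain `"real"` or `"label"`.
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(values, provenance = list(), value_domain = "real") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values))) stop("feature map contains non-finite values")
  if (!value_domain %in% c("real", "label")) {
    stop("`value_domain` must be \"real\" or \"label\"")
  }
  structure(list(values = values, provenance = provenance,
                 value_domain = value_domain),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  prov <- x$provenance
  tag <- paste(vapply(prov, function(v) paste(format(v), collapse = ","),
                      character(1)), collapse = " | ")
  cat(sprintf("<feature_map> %d x %d (%s), range [%.4g, %.4g]\n  %s\n",
              ncol(x$values), nrow(x$values), x$value_domain,
              min(x$values), max(x$values), tag))
  invisible(x)
}

#' @export
dim.feature_map <- function(x) dim(x$values)

#' @export
as.matrix.feature_map <- function(x, ...) x$values

# Internal: accept radiograph / feature_map / matrix, return numeric matrix.
pixel_matrix <- function(x) {
  if (inherits(x, "radiograph")) return(x$pixels)
  if (inherits(x, "feature_map")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a radiograph, feature_map or matrix")
}

# Internal: deterministic round-half-up, used everywhere an integer gray
# level is produced so results do not depend on IEC 60559 round-to-even.
round_half_up <- function(x) floor(x + 0.5)
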