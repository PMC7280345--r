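# Synthetic 12-bit intraoral radiograph phantom: a rounded tooth crown
# (bright enamel rim around mid-intensity dentin) on a dark background
# with an embedded lower-intensity demineralization lesion, plus additive
# Gaussian detector noise. Every operator and the enhancement claim can
# be exercised against known, pixel-exact region masks.

#' Phantom specification
#'
#' Region means are 12-bit intensities ordered
#' `background < dentin < enamel`. The lesion is an ellipse whose
#' intensity is the underlying tissue times `1 - c` (fractional
#' radiodensity drop: mineral loss is multiplicative, not additive).
#' With `gradient = TRUE` (the default) the lesion has the morphology of
#' superficial/medium caries: a demineralized body at full contrast `c`
#' surrounded by a translucent transition zone whose contrast tapers
#' linearly to zero over the outer 35% of the lesion radius. `mottle_sd`
#' adds a fine-grained (about 2 px correlation) multiplicative texture to
#' the demineralized tissue — carious tissue is porous and mottled, which
#' is exactly what histogram-spread features respond to. Gaussian
#' detector noise of sd `noise_sigma` is added last and the result
#' clipped to the 12-bit range.
#'
#' @param width,height image size in pixels.
#' @param background_mean,dentin_mean,enamel_mean region intensities; the
#'   background is rendered as a smooth graded field (scatter and
#'   soft-tissue shadowing) with this mean, spanning roughly 0.1-1.9
#'   times it.
#' @param lesion_center,lesion_axes ellipse centre `(row, col)` and
#'   semi-axes `(row, col)` in pixels.
#' @param lesion_contrast fractional intensity drop `c` in `[0, 1)`
#'   (0 builds a null lesion: the mask exists, the tissue is unchanged).
#' @param gradient logical; body-plus-transition-zone contrast profile
#'   (TRUE) or uniform contrast (FALSE).
#' @param mottle_sd relative sd of the lesion's internal texture field
#'   (0 disables it).
#' @param anatomy_sd relative sd of an optional slowly varying
#'   anatomical-thickness field over the whole tooth (default 0, off).
#' @param noise_sigma Gaussian noise sd in 12-bit intensity units.
#' @param seed integer RNG seed; the phantom is fully deterministic
#'   given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 384L, height = 384L,
                         background_mean = 800, dentin_mean = 3000,
                         enamel_mean = 3700,
                         lesion_center = c(168, 192), lesion_axes = c(52, 40),
                         lesion_contrast = 0.15, gradient = TRUE,
                         mottle_sd = 0.045, anatomy_sd = 0,
                         noise_sigma = 80, seed = 1L) {
  means <- c(background_mean, dentin_mean, enamel_mean)
  if (any(means < 0 | means > 4095)) stop("region means must lie in [0, 4095]")
  if (!(background_mean < dentin_mean && dentin_mean < enamel_mean)) {
    stop("region means must satisfy background < dentin < enamel")
  }
  if (lesion_contrast < 0 || lesion_contrast >= 1) {
    stop("lesion_contrast must lie in [0, 1)")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_mean = background_mean, dentin_mean = dentin_mean,
                 enamel_mean = enamel_mean,
                 lesion_center = lesion_center, lesion_axes = lesion_axes,
                 lesion_contrast = lesion_contrast, gradient = isTRUE(gradient),
                 mottle_sd = mottle_sd, anatomy_sd = anatomy_sd,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized squared elliptical radius of every pixel
ellipse_r2 <- function(H, W, center, axes) {
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  ((r - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2
}

#' Generate a synthetic radiograph phantom
#'
#' Renders the tooth as an ellipse occupying the image centre: an enamel
#' rim band (outer quarter of the elliptical radius), dentin inside it,
#' dark background outside. The lesion ellipse is imposed multiplicatively
#' on the tissue it overlaps and must lie inside the tooth. Noise is drawn
#' under the spec's seed without disturbing the caller's RNG state.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (12-bit `radiograph`), `lesion_mask`, and
#'   `region_masks` (logical matrices `background`, `dentin`, `enamel`,
#'   plus two measurement masks: `reference`, dentin clear of the lesion
#'   and of region boundaries by the default window half-width, and
#'   `lesion_core`, the demineralized body at normalized radius <= 0.8 —
#'   the natural region pair for [enhancement_ratio()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  tooth_center <- c(H / 2, W / 2)
  tooth_axes <- c(0.32 * H, 0.26 * W)
  r2 <- ellipse_r2(H, W, tooth_center, tooth_axes)
  tooth <- r2 <= 1
  enamel <- tooth & r2 > 0.75^2
  dentin <- tooth & !enamel
  background <- !tooth

  lr2 <- ellipse_r2(H, W, spec$lesion_center, spec$lesion_axes)
  lesion <- lr2 <= 1
  if (any(lesion & !tooth)) stop("lesion ellipse extends outside the tooth")

  # the background is a smooth graded field (scatter and soft-tissue
  # shadowing), not a flat level: mean background_mean, range about
  # 0.1x to 1.9x of it across the frame
  u <- 0.6 * (matrix(rep(seq_len(W), each = H), H, W) - 1) / (W - 1) +
       0.4 * (matrix(seq_len(H), H, W) - 1) / (H - 1)
  img <- spec$background_mean * (0.1 + 1.8 * u)
  img[dentin] <- spec$dentin_mean
  img[enamel] <- spec$enamel_mean
  # graded demineralization: a lesion body at full contrast surrounded by
  # a transition (translucent) zone tapering to zero at the rim
  cfac <- if (spec$gradient) {
    spec$lesion_contrast * pmin(1, (1 - sqrt(pmin(lr2, 1))) / 0.35)
  } else matrix(spec$lesion_contrast, H, W)
  img[lesion] <- img[lesion] * (1 - cfac[lesion])

  draws <- local_rng(spec$seed, {
    gh4 <- ceiling(H / 2) + 1L; gw4 <- ceiling(W / 2) + 1L
    gh32 <- ceiling(H / 32) + 1L; gw32 <- ceiling(W / 32) + 1L
    list(mottle = matrix(stats::rnorm(gh4 * gw4), gh4, gw4),
         anatomy = matrix(stats::rnorm(gh32 * gw32), gh32, gw32),
         noise = if (spec$noise_sigma > 0)
           matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W) else NULL)
  })
  if (spec$anatomy_sd > 0) {
    # anatomical noise: slowly varying thickness/superposition variations
    # across the whole tooth (correlation length ~32 px), the structured
    # clutter that makes subtle lesions hard to read on real radiographs
    anat <- bilinear_upsample(draws$anatomy, H, W, spacing = 32)
    img[tooth] <- img[tooth] * (1 + spec$anatomy_sd * anat[tooth])
  }
  if (spec$mottle_sd > 0 && spec$lesion_contrast > 0) {
    # demineralized tissue is porous and mottled, not uniformly darker: a
    # multiplicative field (correlation length ~2 px) modulates the
    # lesion, scaled by the local contrast so it vanishes at the rim
    field <- bilinear_upsample(draws$mottle, H, W, spacing = 2)
    mod <- 1 + spec$mottle_sd * field * cfac / spec$lesion_contrast
    img[lesion] <- img[lesion] * mod[lesion]
  }
  if (!is.null(draws$noise)) img <- img + draws$noise
  img <- pmin(pmax(round_half_up(img), 0), 4095)

  margin <- 10L  # half of the default 21-pixel window
  core <- erode_mask(dentin, margin)
  reference <- core & !dilate_mask(lesion, margin)
  # lesion body: the demineralized core at more than half the nominal
  # contrast, as opposed to the translucent transition margin
  lesion_core <- lr2 <= 0.8^2
  list(image = radiograph(img, 12L, pixel_spacing_mm = 0.018),
       lesion_mask = lesion,
       region_masks = list(background = background, dentin = dentin,
                           enamel = enamel, reference = reference,
                           lesion_core = lesion_core))
}

# bilinear interpolation of a coarse grid onto H x W
bilinear_upsample <- function(g, H, W, spacing = 4) {
  ry <- 1 + (seq_len(H) - 1) / spacing
  rx <- 1 + (seq_len(W) - 1) / spacing
  y0 <- pmin(floor(ry), nrow(g) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(g) - 1L); fx <- rx - x0
  g00 <- g[y0, x0, drop = FALSE]; g01 <- g[y0, x0 + 1L, drop = FALSE]
  g10 <- g[y0 + 1L, x0, drop = FALSE]; g11 <- g[y0 + 1L, x0 + 1L, drop = FALSE]
  fym <- matrix(fy, H, W); fxm <- matrix(fx, H, W, byrow = TRUE)
  (1 - fym) * (1 - fxm) * g00 + (1 - fym) * fxm * g01 +
    fym * (1 - fxm) * g10 + fym * fxm * g11
}

# run expr with a private RNG stream, restoring the caller's state
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# binary erosion/dilation by a (2k+1) square structuring element via
# summed-area tables
box_count <- function(mask, k) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  side <- 2L * k + 1L
  box_mean_reflect(m, side) * side^2
}

erode_mask <- function(mask, k) {
  if (k == 0L) return(mask)
  abs(box_count(mask, k) - (2 * k + 1)^2) < 0.5
}

dilate_mask <- function(mask, k) {
  if (k == 0L) return(mask)
  box_count(mask, k) > 0.5
}

#' Contrast-to-noise enhancement ratio
#'
#' `|mean(map over lesion) - mean(map over reference)|` divided by the
#' pooled standard deviation of the map over the two regions: a
#' dimensionless contrast-to-noise ratio. Computed on the raw input it
#' measures how visible the lesion is to begin with; computed on a
#' texture feature map it measures how much the map enhances (or loses)
#' that visibility.
#'
#' @param map a `feature_map`, `radiograph` or matrix.
#' @param lesion_mask,reference_mask disjoint non-empty logical matrices.
#' @return scalar ratio.
#' @export
enhancement_ratio <- function(map, lesion_mask, reference_mask) {
  v <- pixel_matrix(map)
  if (!any(lesion_mask) || !any(reference_mask)) stop("masks must be non-empty")
  if (any(lesion_mask & reference_mask)) stop("masks must be disjoint")
  a <- as.double(v[lesion_mask]); b <- as.double(v[reference_mask])
  n1 <- length(a); n2 <- length(b)
  s2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (!is.finite(s2) || s2 <= 0) stop("pooled standard deviation is zero")
  abs(mean(a) - mean(b)) / sqrt(s2)
}
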