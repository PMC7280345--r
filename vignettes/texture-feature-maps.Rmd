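---
title: "Texture feature maps for caries-oriented radiograph enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture feature maps for caries-oriented radiograph enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texmap)
```

## The problem

Early carious demineralization appears on intraoral radiographs as a
subtle, low-contrast drop in radiodensity, often at the edge of
detectability against detector noise and overlapping anatomy. Rather than
enhancing the image with a single global transform, this package computes
*texture feature maps*: for every pixel, a statistic of the surrounding
window becomes the new pixel value, so each statistic yields an
alternative rendering of the same radiograph in which particular kinds of
local structure — histogram spread, co-occurrence regularity, run
structure, local energy — are made visible.

## The processing graph

Every output image is produced by one *path*:

1. **Entry transformation** of the 12-bit detector image to the 8-bit
   working image: plain bit-depth reduction (`bit_reduce`), histogram
   equalization first (`histogram_equalize`), or the statistical
   dominance algorithm (`sda`, radius 20, threshold 0, min–max scaled to
   8 bits). Equalization and bit reduction commute to within one gray
   level on smooth images, so their order is immaterial in practice.
2. **Texture operator** over a moving window (21 × 21 by default,
   mirror-reflected at the borders):
   * `FOF` — six first-order histogram statistics (mean, variance,
     skewness, excess kurtosis, energy, entropy), population moments,
     natural-log entropy with a 1e-12 guard;
   * `GLCM` — the fourteen Haralick statistics of the
     distance-1 co-occurrence matrix, four angles summed, both
     directions counted, on the image quantized globally to 32 levels;
   * `GTDM` — the five Amadasun–King gray-tone-difference statistics
     (3 × 3 neighbourhood, on unquantized 8-bit values);
   * `RLM` — eleven run-length statistics (runs along rows and columns
     summed, lengths capped at 10, 32 levels);
   * `LAWS` — nine orientation-pooled texture-energy maps from the 5 × 5
     level/edge/spot/ripple masks;
   * `LBP` — local binary pattern codes, P = 8 samples on radii 5–20,
     bilinear interpolation, strict inequality.
3. **Display post-processing** of real-valued maps: plain min–max 8-bit
   normalization, percentile-clipped histogram stretching (`hstr`), or
   rank-based equalization (`heq_post`). Label-valued maps (LBP codes,
   clustering and quantization renderings) take only the pass-through
   normalization: arithmetic stretching of labels has no meaning.

Intensity clustering (`CLU`, 1-D k-means) and deterministic equal-spacing
quantization (`QNT`) run alongside the windowed operators, rendering each
pixel as its cluster centroid or bin centre so the output is monotone in
intensity and reproducible rather than randomly colored.

`enumerate_paths()` takes the full factorial product; with the default
grids (3 entries × 45 tabulated features × 3 post-processings for the
real-valued operators, plus 16 LBP radii and 5 + 5 cluster counts as
label paths) that is 483 maps per input image. The count is a property of
the configured grids, and `run_batch()` records every output with an MD5
checksum in a manifest so a run can be verified bit-for-bit.

## Numerical conventions

Degenerate inputs never produce NaN: a constant window has variance 0,
energy 1, entropy 0, skewness and kurtosis 0 by convention; co-occurrence
correlation is 0 when a marginal standard deviation vanishes; the
gray-tone-difference coarseness of a constant window saturates at the
sentinel `1/eps` with `eps = 1e-12`; run percentage divides by window
pixels times scan directions; gray-level weights use `level + 1` so
low-gray-level emphases stay finite at level 0. All logarithms are
natural with `0·log 0 := 0`. Sum-indexed Haralick features use 0-based
levels (`k = i + j` in `0..2G-2`); sum variance is taken about the sum
average (the classical printed formula references sum entropy there,
a well-known misprint). The maximal correlation coefficient is the square
root of the second-largest eigenvalue magnitude of the Q matrix, 0 when
fewer than two levels are occupied. Integer outputs round half away from
zero (`floor(x + 0.5)`) everywhere so results cannot depend on
round-to-even.

Quantization bounds are global per image, not per window: two windows
with identical raw content must quantize identically wherever they sit,
otherwise maps are not comparable across the image. Borders are completed
by mirror reflection (edge row included); this preserves local statistics
better than zero padding, at the price of slightly inflated symmetry in a
band up to half a window wide.

The 1-D k-means refines `nstart = 40` seeded random starts plus the
deterministic equal-spacing start and keeps the lowest sum of squared
errors; ties in assignment go to the lower centroid index, an emptied
cluster is re-seeded at the intensity farthest from its centroid, and
convergence is declared when no centroid moves more than 1e-6 or after
100 iterations. Because the first Lloyd step from the equal-spacing
centers reproduces the equal-width partition exactly, the returned fit is
never worse than `equal_spacing_quantize_map()` at the same k — a
guaranteed, not empirical, property.

## The phantom: what it emulates and what it does not

No clinical images ship with the package; every claim is exercised on a
synthetic 12-bit periapical phantom (`generate_phantom()`), 384 × 384 by
default with 0.018 mm pixel spacing:

* a tooth ellipse occupying about a quarter of the frame — an enamel rim
  (mean 3700) around dentin (mean 3000) — over a smooth graded background
  (mean 800, spanning roughly 80–1520) standing in for scatter and
  soft-tissue shadowing; periapical frames are mostly non-tooth, and the
  wide background intensity sweep matters for how intensity clustering
  distributes its centroids;
* an elliptical lesion imposed multiplicatively on the tissue it
  overlaps, with the morphology of superficial/medium caries: a
  demineralized *body* at full fractional contrast `c` (default 0.15)
  inside a *transition zone* whose contrast tapers to zero over the
  outer 35% of the radius;
* fine-grained multiplicative *mottle* (relative sd 0.045, ~2 px
  correlation) inside the lesion, scaled by the local contrast —
  demineralized tissue is porous, and this textural alteration, not just
  the mean drop, is what histogram-spread features detect;
* additive Gaussian detector noise (sd 80 at 12 bits), then clipping.

The generator returns pixel-exact region masks, including the two used
for measurement: `lesion_core` (the body, normalized radius ≤ 0.8) and
`reference` (dentin eroded clear of the lesion and of tissue boundaries
by the 10-px window half-width, so no measured map value mixes tissues).
`enhancement_ratio()` is then a contrast-to-noise ratio: absolute mean
difference between the two regions over their pooled standard deviation.
A map that is constant over both regions has zero pooled sd and raises an
error; verification harnesses record that case as ratio 0, since such a
map displays no contrast.

What the phantom deliberately does **not** model: projection geometry,
beam hardening, scatter kernels, Poisson noise statistics, trabecular
bone texture, tooth roots, or overlapping teeth. Passing the enhancement
checks therefore shows that the operators behave as designed on an image
with the stated statistical structure — it is not clinical validation,
and the directional findings (which maps enhance best) need not transfer
to every real radiograph.

## Verification design

The test suite checks every operator against an independently coded
brute-force oracle (explicit loops over the defining formulas) on random
windows at 1e-9 relative tolerance, the statistical dominance transform
against a double-loop oracle exactly, and closed-form hand-computed
values for degenerate windows. Property tests cover monotonicity of the
intensity remaps, permutation invariance of histogram features, rotation
invariance of the summed co-occurrence matrix, shift equivariance of the
Laws maps, offset invariance of local binary patterns, and determinism of
the full pipeline (identical manifests, including checksums, across two
runs).

The enhancement claim is tested as a directional property on ten seeded
phantoms: the median contrast-to-noise ratio of the first-order energy
map (`FOF-F5`) and of the k = 10 clustering rendering each exceed the raw
image's ratio, while with a null lesion (`c = 0`) all median ratios fall
below 0.5. With the default generator the observed medians are roughly
4.0 (raw), 5.7 (`FOF-F5`) and 5.9 (`CLU`), and null-lesion medians are
0.3 or less; the exact values are recomputed by `scripts/acceptance.R`
at run time, never stored.

Problem sizes used in the checks are chosen to keep a full run on one
CPU in minutes: 200 random 21 × 21 windows per operator family,
32 × 32 images for the statistical-dominance oracle, 64 × 64 smooth
images for the commutation check, a 96 × 96 phantom with reduced grids
for the end-to-end determinism check, and the default 384 × 384 phantom
for the enhancement proxy.

## Known limitations

* The statistical dominance algorithm's dominance relation is
  implemented as non-strict (`>=` with the threshold added to the
  centre); its 8-bit scaling is min–max. Both choices are stated
  contracts of this package rather than community standards.
* The nine Laws maps are the ten orientation-pooled pairs of the four
  kernels minus the pure level map; other selections of "nine" exist in
  the literature.
* Histogram stretching clips at the 0.5th/99.5th percentiles by default;
  rank equalization is used for real-valued maps because binned
  equalization would impose an arbitrary bin width.
* DICOM support is deliberately minimal: single-frame monochrome,
  uncompressed explicit-VR little endian, bits stored 8/12/16. Inverted
  (MONOCHROME1) files are normalized to higher-is-denser at read time.
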