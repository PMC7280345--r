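# texmap

Per-pixel **texture feature maps** for gray-scale intraoral radiographs,
aimed at making subtle carious demineralization visible. Instead of one
globally enhanced image, the package renders one image per texture
statistic: a 21 × 21 window slides over every pixel and the window
statistic becomes the new pixel value.

For a window with normalized intensity histogram H(i) over G gray
levels, the first-order features are the histogram moments — e.g. energy
and entropy,

    F5 = Σᵢ H(i)²        F6 = −Σᵢ H(i) · log(H(i) + ε)

— and the package implements, per window: the six first-order features
(FOF F1–F6), the fourteen Haralick statistics of the distance-1
co-occurrence matrix summed over the four angles at 32 gray levels
(GLCM F1–F14), the five Amadasun–King gray-tone-difference statistics
(GTDM F1–F5), eleven run-length statistics with runs capped at length 10
along 0°/90° (RLM F1–F11), nine Laws texture-energy maps from the 5 × 5
level/edge/spot/ripple masks, and local binary patterns
LBP(P=8, R=5…20) with bilinear circular sampling. Around the operators:
12-to-8-bit reduction, histogram equalization and the statistical
dominance algorithm (radius 20, threshold 0) as entry transformations;
1-D k-means intensity clustering (CLU) and equal-spacing quantization
(QNT) as intensity-grouping maps; min–max normalization, percentile
histogram stretching and rank equalization as display post-processing.
Single-frame monochrome DICOM (12-bit), PNG (8/16-bit) and TIFF
(8/16-bit integer, 32-bit float) I/O with explicit bit-depth handling.

A synthetic 12-bit periapical **phantom** (enamel rim, dentin, graded
background, embedded demineralization lesion with a mottled body and
translucent transition zone, Gaussian detector noise) provides known
ground truth, and `enhancement_ratio()` — a contrast-to-noise ratio
between the lesion body and clean dentin — quantifies how much a map
enhances the lesion relative to the raw radiograph.

## Worked example

```r
library(texmap)

ph  <- generate_phantom(phantom_spec(seed = 42))
ph$image
#> <radiograph> 384 x 384, 12-bit, intensities [0, 4022], spacing 0.018 mm

pre  <- bit_reduce(ph$image)            # 8-bit working image
maps <- fof_maps(pre)                   # six first-order feature maps
maps[["FOF-F5"]]
#> <feature_map> 384 x 384 (real), range [0.02304, 0.07983]
#>   FOF | FOF-F5 | 21

km <- kmeans_intensity(pre, k = 10, seed = 42, init = "random")
km$model
#> <cluster_model> k = 10, SSE = 2.64858e+06, 6 iteration(s), converged
#> centroids: 13.6139, 25.3427, 36.3441, 49.4862, 62.6745, 74.0776,
#>            86.3092, 161.2, 186.201, 230.377

cnr <- function(m) enhancement_ratio(m, ph$region_masks$lesion_core,
                                     ph$region_masks$reference)
c(raw = cnr(ph$image), f5 = cnr(maps[["FOF-F5"]]), clu = cnr(km$map))
#>  raw: 4.09   f5: 5.48   clu: 6.25
```

The lesion body sits at contrast-to-noise 4.1 in the raw radiograph; the
first-order energy map lifts it to 5.5 (the lesion's porous texture
widens the window histogram, lowering energy across the body), and the
k = 10 clustering rendering to 6.3 (the lesion and dentin collapse onto
separate centroids, suppressing noise within each tissue). Centroids
13.6–86.3 tile the graded background; 161.2, 186.2 and 230.4 are the
lesion body, dentin and enamel.

To write every map of the default processing graph (483 per input):

```r
run_batch(list(case1 = ph$image), pipeline_config(), "out/")   # + manifest.csv
```

or from a shell: `Rscript inst/cli/texmap.R run --input case1.dcm --out out/`.

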