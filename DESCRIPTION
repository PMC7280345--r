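Package: texmap
Title: Per-Pixel Texture Feature Maps for Intraoral Radiograph Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-pixel texture feature maps over a moving window on
    gray-scale intraoral radiographs to enhance the visibility of carious
    demineralization. Implements first-order histogram features, the fourteen
    Haralick co-occurrence features, gray-tone-difference (coarseness family)
    features, run-length features, Laws' texture energy measures and local
    binary patterns, together with radiograph preprocessing (bit-depth
    reduction, histogram equalization, the statistical dominance algorithm),
    intensity clustering and quantization maps, display post-processing
    (histogram stretching and rank equalization), full enumeration of
    processing paths, and a synthetic 12-bit radiograph phantom generator
    with a contrast-to-noise enhancement metric for verification. Reads and
    writes single-frame monochrome DICOM, PNG and TIFF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
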