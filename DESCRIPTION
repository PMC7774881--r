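Package: memseg
Title: Deep Watershed Segmentation of Membrane-Stained Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of 2D membrane-stained epithelial tissues by a
    watershed-target convolutional network. A curated watershed segmentation is
    encoded into seven aligned training targets (the one-pixel watershed mask,
    two dilated copies, their negatives, size-scaled per-cell seeds and the
    seed negative); a compact LinkNet-style encoder-decoder is trained with a
    soft Jaccard loss to reproduce all seven from the raw image; the seven
    predicted maps are decoded through classical and seeded watershed
    transforms and fused by majority vote into a refined one-pixel boundary
    mask. Includes deterministic Vincent-Soille watershed primitives, paired
    geometric augmentation, tiled inference with exactly-once stitching, SEG
    and average-precision instance metrics, and a synthetic Voronoi epithelium
    generator so the full pipeline is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
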