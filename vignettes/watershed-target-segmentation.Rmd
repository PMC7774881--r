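---
title: "Segmenting membrane-stained epithelia with watershed targets"
author: "memseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting membrane-stained epithelia with watershed targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memseg)
```

## The problem and the model

Epithelial biology starts from a segmentation: every cell of a
membrane-stained tissue must be outlined before shapes, neighbour topology or
dynamics can be quantified. Classical seeded-watershed tools do this well on
clean images but need extensive manual curation on hard ones — dotted
junctional staining in embryos, low boundary-to-cytoplasm contrast, or
tissues mixing giant polyploid cells with tiny histoblast-like cells.

`memseg` implements a watershed-target learning pipeline around a
convolutional encoder–decoder:

1. **Encode** (`encode_targets`): a curated watershed segmentation (an
   integer label image whose 0-pixels are the one-pixel watershed lines) is
   expanded into seven aligned binary targets: the boundary mask itself, the
   mask after one and two 3×3 binary dilations, the pixelwise negatives of
   the two dilated masks, one seed per cell scaled with cell size, and the
   seed negative.
2. **Learn** (`build_model`, `train_model`): a LinkNet-style network (VGG16
   conv-block encoder, mirrored decoder, additive skips, sigmoid head) is
   trained to emit all seven maps from the raw image, with a soft Jaccard
   (IoU) loss averaged over the channels.
3. **Decode and fuse** (`targets_to_masks`, `fuse_masks`): each predicted
   map is converted back into a one-pixel watershed mask — boundary-type
   channels by flooding them as height maps, negatives after inversion,
   seed channels by seeded flooding of the mean boundary probability — and
   the seven masks are averaged and thresholded (majority vote), then
   re-closed into a valid partition.
4. **Score** (`seg_score`, `average_precision`): agreement with ground truth
   is quantified by SEG (mean IoU of >half-overlap matches) and AP =
   TP/(TP+FP+FN) with one-to-one matches at IoU ≥ 0.7.

The redundancy of the seven targets is the point: each decoded mask makes
*different* mistakes (a spurious minimum in one probability map rarely has a
counterpart in the others), so the majority vote erases them while unanimous
structure — the true junctional network — survives.

## Watershed conventions

All flooding is done by one deterministic Meyer/Vincent–Soille
implementation with explicit watershed lines:

* basins grow with 4-connectivity, so cells are 4-connected regions and
  lines are 8-connected curves;
* queue priority is (height, plateau key, insertion order), where the
  plateau key of a pixel is its chessboard BFS distance, inside its
  equal-height plateau, to the plateau's strictly-lower boundary. Fronts
  entering a plateau therefore advance at equal chessboard speed, and a band
  produced by chebyshev (3×3) dilation of a curve is divided exactly on the
  original curve, for every curve orientation. A plain FIFO ordering gets
  this wrong by one pixel on diagonal staircases — the chessboard key is
  what makes the dilated channels decode onto the encoding boundary;
* a popped pixel is assigned if exactly one label is visible among its
  decided 4-neighbours, and becomes a line pixel when two fronts meet
  (or when it is never reached). Line pixels do not extend fronts.

Under these rules the transform is idempotent on its own output:
re-flooding the regions delimited by a produced mask reproduces the mask
(`is_canonical_boundary`). The image border always acts as a closing wall
for region extraction, so border-touching cells are well-defined regions;
painting the physical frame is available (`close_border = TRUE`) but off by
default because it would alter region membership of border cells and break
the labels↔boundary round-trip.

Unseeded flooding starts from regional minima, optionally after h-minima
suppression. When decoding *predicted* (non-binary) maps, a small default
`hmin = 0.05` removes sub-5 % confidence ripples inside cells that would
otherwise nucleate spurious basins; binary inputs are unaffected since their
minima are 1 deep.

## Why the codec round-trip is exact

Feeding the encoder's own seven targets through the decoder recovers the
source partition pixel-for-pixel (SEG = 1.0, AP = 1.0). Three ingredients
make this exact rather than approximate:

* the flooding conventions above (ties land on the encoded line);
* the fusion vote: masks decoded from different channels disagree only
  where a channel is individually ambiguous, and such pixels never reach
  the 4-of-7 majority;
* the synthetic ground truth itself is *codec-canonical*: the generator
  computes the Voronoi partition (as the seeded watershed of the exact
  Euclidean distance-to-centre field, which yields watershed lines rather
  than a fully-painted labeling) and then iterates `decode(encode(·))` to
  its fixed point — in practice 2–3 iterations that only move one or two
  pixels at three-cell junctions, preserving cell counts. Re-division of
  merged dilation bands at junctions is discretely ambiguous, so *some*
  convention had to be fixed; taking the codec's own fixed point mirrors
  how real training data are made (curated masks are themselves watershed
  outputs) and makes "exact recovery" a well-posed property.

## The synthetic epithelium generator

`generate_tissue` emulates the statistical structure of membrane-stained
fly epithelia so that training, inference, fusion and metrics are testable
without any external data:

* **Geometry** — cell centres are a Poisson point process (default density
  50 cells per 10⁴ px ≈ 16 px cell diameter, typical of confocal epithelium
  fields), regularized by 2 Lloyd iterations; ground truth is the watershed
  of the distance-to-centre field, canonicalized as above. A weighted
  mixture (`size_mixture`) emulates giant polyploid cells surrounded by
  tiny histoblast-like cells via multiplicatively-weighted Voronoi scales.
* **Staining** — `continuous` junctions (pupal-wing-like; boundary drawn at
  `boundary_intensity = 0.8` over `cytoplasm_intensity = 0.15`) or `dotted`
  junctions (embryonic E-cadherin-like puncta: boundary points thinned to a
  fixed spacing and rendered as Gaussian beads). The
  boundary-to-cytoplasm ratio is the contrast dial.
* **Optics and noise** — Gaussian PSF blur (default σ = 1 px), additive
  Gaussian noise (default sd = 0.05), optional Poisson shot noise, and a
  linear illumination gradient (default ±10 %).

What the generator does *not* emulate: curved-tissue projection artifacts,
out-of-focus light from neighbouring z-planes, anisotropic PSFs, membrane
intensity fluctuations along a single junction, and cytoplasmic organelle
texture. Tests passing on synthetic tissues therefore demonstrate the
correctness of the machinery and the learnability of the mapping, not
performance on any particular real microscope image.

## Network, loss and training scale

The paper-scale profile follows the published recipe exactly: LinkNet with
a VGG16-style encoder (conv counts 2,2,3,3,3; widths 64–512), tile 256,
batch 24, 300 epochs of Adam at 10⁻³ for 150 epochs then 10⁻⁴. Because no
deep-learning framework is available in this stack, the layers
(im2col/GEMM convolutions, max-pool, nearest upsample), Adam and the loss
are implemented in the package itself (RcppArmadillo); gradients are
verified against central differences in the test suite.

Two departures from a naive reading, both standard practice:

* **Instance normalization** after every convolution except the output
  head. Public LinkNet implementations normalize activations in encoder
  and decoder blocks; with a from-scratch (non-pretrained) encoder and a
  pure Jaccard loss, the unnormalized network reliably collapses into the
  saturated all-ones local optimum of the loss (the loss rewards
  predicting the majority value of every channel, sigmoids saturate, and
  gradients die). Per-sample instance norm needs no running statistics,
  keeps inference deterministic, and removes the collapse. The sigmoid
  output is additionally clamped to [10⁻⁷, 1−10⁻⁷] so saturated pixels
  keep a live gradient.
* **The `tiny` preset** (encoder conv counts 1,1,2,2,2, widths scaled by
  1/8, tile 64, batch 4) is the test-suite workhorse: it trains on one CPU
  in minutes. The end-to-end fixture trains it for 100 epochs (10⁻³ then
  10⁻⁴ from epoch 51) on 32 tiles of 64 px cut from eight 128×128 synthetic
  tissues, and evaluates the full predict→decode→fuse→label pipeline on
  eight held-out tissues.

The soft Jaccard loss uses `eps = 1` smoothing and averages the per-channel
indices (the multi-output reduction is not specified by the recipe; the
flattened-tensor alternative is available via `per_channel = FALSE`).
Checkpointing keeps the best-training-loss weights; no validation split is
carved out by default (an explicit holdout is the caller's choice), matching
the published schedule which trains on the complete set every epoch.

## Tiled inference

Large images are reflect-padded (mirror indexing that folds for pads larger
than the image) and cut into overlapping tiles; each pixel of the output is
taken from the tile in whose central crop it falls, so every pixel is
written exactly once and no blending is needed. The default overlap of 32 px
at tile 256 discards a 16 px margin per tile edge, which exceeds the
effective receptive-field contamination of the padded borders in practice.
Feathered blending was deliberately rejected: exactly-once semantics make
the stitching invariance testable (a translation-equivariant stub must give
layout-independent output, and does).

## Numerical choices and degenerate inputs

* Percentile normalization uses the inverse empirical CDF
  (`quantile(type = 1)`), mapping requested percentiles onto observed pixel
  values; defaults 1–99.9 % are robust to hot pixels. Constant images map
  to zeros.
* Seed radius follows `max(1, floor(0.2 * sqrt(area)))` — proportional to
  cell diameter, as a size-scaled seed should be; the factor is exposed
  (`seed_scale`). Seeds are clipped to stay clear of the twice-dilated
  boundary; a cell too small for that degrades to its farthest interior
  pixel and, if even that pixel is inside the dilated band, the cell is
  reported in a warning attribute rather than raising an error.
* The farthest-interior seed centre breaks distance ties toward the cell
  centroid before raster order. Squared grid distances are integers, so
  ties are common; the centroid criterion keeps seed placement equivariant
  under flips and quarter-turns, which is what makes
  `encode(flip(L)) == flip(encode(L))` hold exactly.
* Fusion re-closure floods the negated distance-to-candidate map with
  `h = 1` minima suppression: sub-pixel distance plateaus inside a cell
  must not split it, while genuine cells (inradius > 1 px) must stay
  separate basins. The same step closes small gaps the vote may have opened
  and deletes isolated false-positive line islands.
* A seed channel that binarizes to nothing falls back to unseeded flooding
  of the mean boundary probability and is reported in a `fallbacks`
  attribute (and as a message in the CLI), never silently dropped.

## Known limitations

* Training at the paper scale (tile 256, batch 24, 300 epochs) is far
  outside a single-CPU budget; the implementation accepts the profile but
  realistic use of this package's trainer is the tiny/CPU scale. The
  architecture is fixed to the 7-output LinkNet; alternative backbones are
  out of scope.
* The augmentation family is the four named transforms (rotation,
  translation, zoom, flips) plus intensity jitter; elastic deformations and
  noise injection are not implemented.
* z-stacks are rejected rather than projected; projection quality is a
  large topic of its own and upstream of this package.
* Greedy AP matching is exact only for IoU thresholds ≥ 0.5 (each cell can
  exceed 0.5 IoU with at most one partner); below that it is a heuristic,
  and the brute-force oracle in the tests covers the default 0.7 regime.

## A worked micro-example

```{r example, eval = FALSE}
smp <- generate_tissue(tissue_params(field = c(128L, 128L), rng_seed = 1))
targets <- encode_targets(smp$truth)
recovered <- decode_targets(as_prediction(targets))
average_precision(smp$truth, recovered)
#> <match_report: SEG 1.0000 | AP 1.0000 (TP 76, FP 0, FN 0)>
```

The same pipeline with a trained model replaces the perfect targets by
`predict_tiled(model, image)`; `scripts/acceptance.R` runs that end-to-end
experiment from scratch at the tiny scale and reports the resulting SEG and
AP.
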