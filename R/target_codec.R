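# Seven-channel target codec: encode a curated label image into the seven
# training targets, and decode/fuse seven predicted probability maps into a
# refined one-pixel watershed mask.
#
# Channel roles (fixed order):
#   1 mask      one-pixel watershed boundary
#   2 mask_dil1 boundary after one 3x3 binary dilation
#   3 mask_dil2 boundary after two 3x3 binary dilations
#   4 neg_dil1  1 - mask_dil1
#   5 neg_dil2  1 - mask_dil2
#   6 seeds     one size-scaled seed per cell, strictly interior
#   7 neg_seeds 1 - seeds

.CHANNEL_ROLES <- c("mask", "mask_dil1", "mask_dil2", "neg_dil1", "neg_dil2",
                    "seeds", "neg_seeds")

#' Construct a seven-channel target stack
#'
#' @param channels H x W x 7 numeric array (binary for targets, \[0, 1\] for
#'   predictions).
#' @param flavor `"target"` or `"prediction"`.
#' @return A `target_stack` array with channel roles in `dimnames`.
#' @export
target_stack <- function(channels, flavor = c("target", "prediction")) {
  flavor <- match.arg(flavor)
  if (length(dim(channels)) != 3L || dim(channels)[3L] != 7L) {
    stop("a target stack has exactly 7 same-shape channels")
  }
  if (any(channels < 0 | channels > 1)) {
    stop("target stack values must lie in [0, 1]")
  }
  if (flavor == "target" && !all(channels %in% c(0, 1))) {
    stop("target-flavor stacks must be binary")
  }
  dimnames(channels) <- list(NULL, NULL, .CHANNEL_ROLES)
  structure(channels, flavor = flavor, class = c("target_stack", "array"))
}

#' @export
print.target_stack <- function(x, ...) {
  cat(sprintf("<target_stack %s: %d x %d x 7 [%s]>\n", attr(x, "flavor"),
              dim(x)[1], dim(x)[2], paste(.CHANNEL_ROLES, collapse = ", ")))
  invisible(x)
}

#' Reinterpret a target stack as a prediction
#'
#' Casts binary targets to probabilities, e.g. to exercise the decode path on
#' perfect predictions.
#' @param s A `target_stack`.
#' @return The same stack with `flavor = "prediction"`.
#' @export
as_prediction <- function(s) {
  stopifnot(inherits(s, "target_stack"))
  attr(s, "flavor") <- "prediction"
  s
}

#' Fusion configuration
#'
#' @param threshold Vote threshold in (0, 1) applied to the weighted mean of
#'   the seven decoded masks; the default 0.5 is a strict majority of 7.
#' @param seed_binarize_level Level in (0, 1) at which seed-channel
#'   probabilities are binarized before seeded flooding.
#' @param weights Seven non-negative per-mask weights (default all 1).
#' @param hmin h-minima depth used when flooding predicted probability maps;
#'   suppresses sub-`hmin` confidence ripples inside cells. Binary inputs are
#'   unaffected by the default 0.05.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(threshold = 0.5, seed_binarize_level = 0.5,
                          weights = rep(1, 7), hmin = 0.05) {
  stopifnot(threshold > 0, threshold < 1,
            seed_binarize_level > 0, seed_binarize_level < 1,
            length(weights) == 7L, all(weights >= 0), sum(weights) > 0,
            hmin >= 0)
  structure(list(threshold = threshold,
                 seed_binarize_level = seed_binarize_level,
                 weights = as.numeric(weights), hmin = hmin),
            class = "fusion_config")
}

#' Encode a label image into the seven training targets
#'
#' Builds the one-pixel boundary mask, its one- and two-step 3x3 dilations,
#' the two negatives, one seed disk per cell and the seed negative. Each seed
#' is a disk of radius `max(1, floor(seed_scale * sqrt(area)))` centred at
#' the cell's interior point farthest from the boundary (inscribed-circle
#' centre, raster tie-break), clipped so it never touches `mask_dil2`. A cell
#' too small to host such a seed degrades to its single farthest-interior
#' pixel; cells whose fallback pixel still lies in `mask_dil2` are listed in
#' the `seed_warnings` attribute (one seed is still placed).
#'
#' @param labels Integer label image satisfying the label-image invariants.
#' @param seed_scale Scale factor `c` of the seed-radius law (default 0.2).
#' @return A target-flavor `target_stack` with attribute `seed_warnings`.
#' @export
encode_targets <- function(labels, seed_scale = 0.2) {
  .stopifnot_matrix(labels)
  storage.mode(labels) <- "integer"
  nlab <- max(labels, 0L)
  if (nlab < 1L) stop("label image has no cells")

  ch1 <- labels_to_boundary(labels)
  ch2 <- .dilate3(ch1)
  ch3 <- .dilate3(ch2)

  # distance of every cell pixel to the boundary/frame
  D <- .distmap_padded(labels > 0)
  allowed <- (labels > 0) & !ch3

  areas <- tabulate(labels[labels > 0], nbins = nlab)
  seeds <- matrix(FALSE, nrow(labels), ncol(labels))
  warn <- integer()

  nr <- nrow(labels)
  for (lab in seq_len(nlab)) {
    if (areas[lab] == 0L) next
    idx <- which(labels == lab)
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    # farthest interior point; ties broken by closeness to the centroid
    # (flip/rot90-equivariant), then raster order
    d2c <- (r - mean(r))^2 + (c - mean(c))^2
    ord <- order(-D[idx], d2c, r, c)
    ctr <- ord[1L]
    rad <- max(1, floor(seed_scale * sqrt(areas[lab])))
    disk <- which((r - r[ctr])^2 + (c - c[ctr])^2 <= rad^2)
    ok <- disk[allowed[idx[disk]]]
    if (length(ok) == 0L || !allowed[idx[ctr]]) {
      # degenerate cell: single farthest-interior pixel
      seeds[idx[ctr]] <- TRUE
      if (ch3[idx[ctr]]) warn <- c(warn, lab)
    } else {
      m <- matrix(FALSE, nrow(labels), ncol(labels))
      m[idx[ok]] <- TRUE
      # keep the 4-connected piece containing the centre
      cc <- .cc_label(m, 4L)
      keep <- cc == cc[idx[ctr]] & cc > 0L
      if (!keep[idx[ctr]]) keep[idx[ctr]] <- TRUE
      seeds <- seeds | keep
    }
  }

  chans <- array(0, dim = c(nrow(labels), ncol(labels), 7L))
  chans[, , 1] <- ch1 * 1
  chans[, , 2] <- ch2 * 1
  chans[, , 3] <- ch3 * 1
  chans[, , 4] <- 1 - chans[, , 2]
  chans[, , 5] <- 1 - chans[, , 3]
  chans[, , 6] <- seeds * 1
  chans[, , 7] <- 1 - chans[, , 6]
  out <- target_stack(chans, "target")
  attr(out, "seed_warnings") <- warn
  out
}

# Mean of the boundary-oriented probabilities (negatives inverted).
.boundary_mean <- function(s) {
  (s[, , 1] + s[, , 2] + s[, , 3] + (1 - s[, , 4]) + (1 - s[, , 5])) / 5
}

#' Decode seven predicted maps into seven watershed masks
#'
#' Boundary-type channels (1-3) are used directly as watershed height maps;
#' negative channels (4, 5) are inverted first. Each seed channel (6 and the
#' inverted 7) is binarized at `cfg$seed_binarize_level` and used to run a
#' seeded watershed on the mean boundary-oriented probability; the resulting
#' partition's boundary is that channel's mask. A seed channel that binarizes
#' to zero seeds falls back to the unseeded watershed of the mean boundary
#' probability; such events are recorded in the `fallbacks` attribute.
#'
#' @param s Prediction-flavor `target_stack`.
#' @param cfg A [fusion_config()].
#' @return List of 7 logical boundary masks with attribute `fallbacks`.
#' @export
targets_to_masks <- function(s, cfg = fusion_config()) {
  stopifnot(inherits(s, "target_stack"))
  if (!identical(attr(s, "flavor"), "prediction")) {
    stop("targets_to_masks expects a prediction-flavor stack; see as_prediction()")
  }
  bmean <- .boundary_mean(s)
  masks <- vector("list", 7L)
  fallbacks <- integer()
  for (k in 1:3) masks[[k]] <- watershed_lines(s[, , k], h = cfg$hmin)
  for (k in 4:5) masks[[k]] <- watershed_lines(1 - s[, , k], h = cfg$hmin)
  for (k in 6:7) {
    p <- if (k == 6L) s[, , 6] else 1 - s[, , 7]
    sd_bin <- p >= cfg$seed_binarize_level
    if (!any(sd_bin)) {
      masks[[k]] <- watershed_lines(bmean, h = cfg$hmin)
      fallbacks <- c(fallbacks, k)
    } else {
      lab <- seeded_watershed(bmean, sd_bin)
      masks[[k]] <- labels_to_boundary(lab)
    }
  }
  names(masks) <- .CHANNEL_ROLES
  attr(masks, "fallbacks") <- fallbacks
  masks
}

#' Fuse seven watershed masks into a refined boundary mask
#'
#' Takes the weighted pixelwise mean of the seven masks, keeps pixels whose
#' vote exceeds `cfg$threshold` as candidate boundary, then re-closes and
#' re-skeletonizes the candidate by flooding the negated distance-to-candidate
#' map, so the output is a valid closed one-pixel partition even when voting
#' breaks curves. An all-empty candidate returns an empty mask.
#'
#' @param masks List of 7 same-shape binary/logical masks.
#' @param cfg A [fusion_config()].
#' @return Logical refined boundary mask.
#' @export
fuse_masks <- function(masks, cfg = fusion_config()) {
  stopifnot(is.list(masks), length(masks) == 7L)
  d <- dim(masks[[1]])
  w <- cfg$weights
  acc <- matrix(0, d[1], d[2])
  for (k in 1:7) {
    mk <- masks[[k]]
    if (!all(dim(mk) == d)) stop("masks must share one shape")
    acc <- acc + w[k] * (mk > 0)
  }
  vote <- acc / sum(w)
  candidate <- vote > cfg$threshold
  if (!any(candidate)) return(candidate)
  refined <- watershed_lines(-.dist_to_set(candidate), h = 1.0)
  refined
}

#' Label image of a refined boundary mask
#'
#' Final decode step: delegates to [boundary_to_labels()].
#' @param boundary Logical boundary mask.
#' @return Integer label image.
#' @export
refined_mask_to_labels <- function(boundary) boundary_to_labels(boundary)

#' Full decode: prediction stack to label image
#'
#' Convenience composition of [targets_to_masks()], [fuse_masks()] and
#' [refined_mask_to_labels()].
#' @inheritParams targets_to_masks
#' @return Integer label image.
#' @export
decode_targets <- function(s, cfg = fusion_config()) {
  refined_mask_to_labels(fuse_masks(targets_to_masks(s, cfg), cfg))
}

#' Write / read a target stack as a 7-page TIFF
#'
#' Pages follow the fixed channel-role order; values are stored as 32-bit
#' samples scaled to \[0, 1\].
#' @param path File path.
#' @param s A `target_stack`.
#' @export
write_targets <- function(path, s) {
  stopifnot(inherits(s, "target_stack"))
  pages <- lapply(1:7, function(k) matrix(s[, , k], dim(s)[1], dim(s)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_targets
#' @param flavor Flavor to stamp on the stack read back.
#' @export
read_targets <- function(path, flavor = c("prediction", "target")) {
  flavor <- match.arg(flavor)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 7L) stop("expected a 7-page TIFF, got ", length(pages))
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], 7L))
  for (k in 1:7) arr[, , k] <- pages[[k]]
  if (flavor == "target") arr <- round(arr)
  target_stack(arr, flavor)
}
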