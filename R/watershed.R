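# Classical and seeded watershed primitives.
#
# All flooding goes through a deterministic Vincent-Soille implementation
# (src/flood.cpp): basins are 4-connected, plateaus are divided synchronously
# by BFS generation so equidistant fronts tie exactly, ties and unreached
# pixels become one-pixel watershed lines, and the transform is idempotent on
# its own line output. Line pixels use 8-connectivity as curves; regions are
# 4-connected.

#' Watershed lines of a height map
#'
#' Floods `height` from its regional minima (optionally after h-minima
#' suppression) and returns the binary one-pixel watershed-line mask. Each
#' complement region contains exactly one regional minimum.
#'
#' @param height Numeric matrix, finite.
#' @param h Non-negative h-minima depth: regional minima shallower than `h`
#'   (relative to their merging saddle) are suppressed before flooding.
#'   `h = 0` floods from the raw minima.
#' @return Logical matrix; `TRUE` marks watershed-line pixels.
#' @export
watershed_lines <- function(height, h = 0) {
  .stopifnot_matrix(height)
  if (any(!is.finite(height))) stop("height map must be finite")
  storage.mode(height) <- "double"
  if (h > 0) height <- .reconstruct_erosion(height + h, height)
  minima <- .regional_minima(height)
  lab <- .flood_ws(height, minima)
  lab == 0L
}

#' Seeded watershed
#'
#' Floods `height` from the supplied seeds; every pixel receives the label of
#' the seed whose flood reaches it first, and pixels where two fronts meet
#' become watershed-line pixels (label 0). The number of positive labels in
#' the result equals the number of 4-connected seed components.
#'
#' @param height Numeric matrix, finite.
#' @param seeds Logical/binary matrix of seed pixels, or an integer matrix of
#'   pre-labelled seeds (0 = no seed).
#' @return Integer label image; watershed-line pixels are 0.
#' @export
seeded_watershed <- function(height, seeds) {
  .stopifnot_matrix(height)
  .stopifnot_matrix(seeds)
  if (any(!is.finite(height))) stop("height map must be finite")
  if (!all(dim(height) == dim(seeds))) stop("height and seeds shapes differ")
  storage.mode(height) <- "double"
  if (is.logical(seeds) || .is_binary(seeds)) {
    seedlab <- .cc_label(seeds > 0, 4L)
  } else {
    seedlab <- seeds
    storage.mode(seedlab) <- "integer"
  }
  if (!any(seedlab > 0)) stop("seeded_watershed requires at least one seed")
  .flood_ws(height, seedlab)
}

#' Boundary mask of a label image
#'
#' Marks the 0-pixels that touch (8-connectivity) at least one positive
#' label. The image border always acts as a closing wall for region
#' extraction ([boundary_to_labels()] labels components inside the frame);
#' `close_border = TRUE` additionally paints the physical one-pixel frame,
#' which is useful for display/export but changes region membership of
#' border-touching cells.
#'
#' @param labels Integer label image.
#' @param close_border Paint the image frame as boundary (default `FALSE`).
#' @return Logical boundary mask.
#' @export
labels_to_boundary <- function(labels, close_border = FALSE) {
  .stopifnot_matrix(labels)
  pos <- labels > 0
  b <- (!pos) & .dilate3(pos)
  if (close_border) {
    b[1, ] <- TRUE; b[nrow(b), ] <- TRUE
    b[, 1] <- TRUE; b[, ncol(b)] <- TRUE
  }
  b
}

#' Label the cells delimited by a boundary mask
#'
#' Labels the 4-connected components of the complement of `boundary` with
#' consecutive integers in raster-scan (row, col) order of each component's
#' first pixel. The frame acts as a wall, so cells touching the border are
#' closed regions.
#'
#' @param boundary Logical/binary boundary mask.
#' @return Integer label image; boundary pixels are 0.
#' @export
boundary_to_labels <- function(boundary) {
  .stopifnot_matrix(boundary)
  .cc_label(!(boundary > 0), 4L)
}

#' Check that a boundary mask is watershed-canonical
#'
#' A canonical mask is one pixel wide in the watershed sense: re-flooding the
#' regions it delimits reproduces the mask exactly, i.e. every line pixel
#' either separates two distinct regions in its 4-neighbourhood or is an
#' enclosed junction-cluster pixel, and no line pixel can be absorbed into a
#' region. Masks produced by [watershed_lines()], [seeded_watershed()] and
#' [fuse_masks()] satisfy this by construction.
#'
#' @param boundary Logical boundary mask.
#' @return `TRUE` if canonical, `FALSE` otherwise.
#' @export
is_canonical_boundary <- function(boundary) {
  .stopifnot_matrix(boundary)
  lab <- boundary_to_labels(boundary)
  relined <- .flood_ws(matrix(as.double(boundary > 0), nrow(boundary)), lab)
  identical(relined == 0L, boundary > 0)
}
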