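# Reading, writing and normalizing microscopy images and label images.
#
# Conventions: images are base R numeric matrices indexed (row, col), 0-based
# in documentation, 1-based in R code; label images are integer matrices in
# which 0 marks watershed-line/background pixels and each cell is one
# 4-connected positive label.

#' Read a grayscale microscopy image
#'
#' Reads a single-page TIFF or a PNG as a numeric matrix holding the original
#' bit-depth values as reals (e.g. 0..65535 for a 16-bit TIFF). Colour images
#' are converted to grayscale by the unweighted mean of the first three
#' channels. Multi-page TIFFs (z-stacks) are rejected: projection is a
#' preprocessing step outside this package's scope.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix with attribute `bit_depth` (source bits per
#'   sample, `NA` when unknown).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pages) > 1L) {
      stop("z-stacks unsupported; project first (", path, " has ",
           length(pages), " pages)")
    }
    x <- pages[[1L]]
    depth <- attr(x, "bits.per.sample")
    if (is.null(depth)) depth <- NA_integer_
  } else if (ext == "png") {
    x <- png::readPNG(path)
    depth <- .png_bit_depth(path)
    x <- x * (2^depth - 1)  # back to original code values
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         " (use TIFF or PNG)")
  }
  if (length(dim(x)) == 3L) {
    nch <- min(dim(x)[3L], 3L)  # drop alpha if present
    x <- apply(x[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  x <- matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
  if (any(!is.finite(x))) stop("image contains non-finite pixel values: ", path)
  attr(x, "bit_depth") <- as.integer(depth)
  x
}

# Bit depth lives at byte 25 of the PNG IHDR chunk.
.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])
}

#' Percentile-normalize an intensity image to the unit interval
#'
#' Linearly rescales so that the `low_pct` percentile maps to 0 and the
#' `high_pct` percentile maps to 1, then clips to \[0, 1\]. Percentiles use the
#' inverse empirical CDF (`quantile(type = 1)`), which is robust to hot pixels
#' and maps a requested percentile onto an observed pixel value. A constant
#' image maps to all zeros.
#'
#' @param img Numeric matrix.
#' @param low_pct,high_pct Percentiles in \[0, 100\], `low_pct < high_pct`.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
normalize_image <- function(img, low_pct = 1, high_pct = 99.9) {
  .stopifnot_matrix(img)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  if (any(!is.finite(img))) stop("image contains non-finite pixel values")
  q <- quantile(as.vector(img), c(low_pct, high_pct) / 100,
                type = 1, names = FALSE)
  if (q[2] <= q[1]) {
    out <- matrix(0, nrow(img), ncol(img))
  } else {
    out <- .clip01((img - q[1]) / (q[2] - q[1]))
  }
  attr(out, "bit_depth") <- attr(img, "bit_depth")
  out
}

#' Read an integer label image from TIFF
#'
#' @param path Path to an integer-valued TIFF (8/16/32-bit unsigned).
#' @return Integer matrix; 0 is the watershed-line/background value.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read labels: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) > 1L) stop("label image must be single-page: ", path)
  x <- pages[[1L]]
  fmt <- attr(x, "sample.format")
  if (!is.null(fmt) && identical(fmt, "float")) {
    stop("label image must be integer-valued, got float TIFF: ", path)
  }
  if (length(dim(x)) == 3L) stop("label image must be single-channel: ", path)
  if (any(x != round(x))) {
    stop("label image must be integer-valued, got fractional pixels: ", path)
  }
  matrix(as.integer(round(x)), nrow = nrow(x), ncol = ncol(x))
}

#' Write an integer label image as a 32-bit TIFF
#'
#' Round-trips losslessly through [read_labels()] for labels up to 2^31 - 1.
#'
#' @param path Output path.
#' @param labels Integer matrix of non-negative labels.
#' @export
write_labels <- function(path, labels) {
  .stopifnot_matrix(labels)
  if (any(labels < 0)) stop("labels must be non-negative")
  tiff::writeTIFF(labels / (2^32 - 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a unit-interval intensity image as a 16-bit TIFF
#' @param path Output path.
#' @param img Numeric matrix with values in \[0, 1\].
#' @export
write_image <- function(path, img) {
  .stopifnot_matrix(img)
  tiff::writeTIFF(.clip01(img), path, bits.per.sample = 16L)
  invisible(path)
}

#' Validate the label-image invariants
#'
#' Checks that labels are non-negative integers, that every positive label
#' forms exactly one 4-connected component, and that distinct positive labels
#' are never 4-adjacent (watershed-line convention: at least one 0-pixel
#' separates any two cells).
#'
#' @param labels Integer matrix.
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validate_labels <- function(labels) {
  .stopifnot_matrix(labels)
  probs <- character()
  if (any(labels < 0)) probs <- c(probs, "negative labels present")
  pos <- sort(unique(labels[labels > 0]))
  if (length(pos)) {
    cc <- .cc_label(labels > 0, 4L)
    # each positive label must live inside exactly one 4-component, and no
    # 4-component may host two labels (4-adjacent distinct labels)
    map <- unique(data.frame(lab = labels[labels > 0], cc = cc[labels > 0]))
    if (anyDuplicated(map$lab)) {
      probs <- c(probs, "some label occupies more than one 4-connected component")
    }
    if (anyDuplicated(map$cc)) {
      probs <- c(probs, "distinct labels are 4-adjacent (missing separating 0-pixel)")
    }
  }
  if (length(probs)) probs else TRUE
}
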