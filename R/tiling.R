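# Tiled inference: decompose an arbitrarily large image into overlapping
# fixed-size tiles, predict each, and stitch by central cropping so every
# output pixel is written exactly once.

#' Plan the tiling of an image
#'
#' Windows stride by `tile_size - overlap`; the image is reflect-padded
#' (mirror without edge repetition, folding for pads larger than the image)
#' by `overlap / 2` on the leading edges plus whatever the last window needs.
#' The central `stride x stride` crops of the windows cover the original
#' image exactly once.
#'
#' @param shape Integer vector `c(rows, cols)` of the image.
#' @param tile_size Tile side, divisible by 32.
#' @param overlap Even non-negative overlap, `< tile_size / 2`.
#' @return A `tiling_plan` with the window list (0-based, half-open) and pad
#'   amounts.
#' @export
plan_tiles <- function(shape, tile_size = 256L, overlap = 32L) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (tile_size %% 32L != 0L) stop("tile_size must be divisible by 32")
  if (overlap %% 2L != 0L || overlap < 0L || overlap >= tile_size / 2) {
    stop("overlap must be even, non-negative and < tile_size / 2")
  }
  stride <- tile_size - overlap
  n <- as.integer(ceiling(shape / stride))
  padded <- n * stride + overlap
  pad_lead <- c(overlap / 2, overlap / 2)
  pad_trail <- padded - shape - pad_lead
  grid <- expand.grid(kr = seq_len(n[1]) - 1L, kc = seq_len(n[2]) - 1L)
  windows <- data.frame(row0 = grid$kr * stride, col0 = grid$kc * stride)
  windows$row1 <- windows$row0 + tile_size
  windows$col1 <- windows$col0 + tile_size
  structure(list(tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), stride = as.integer(stride),
                 shape = as.integer(shape), n = n,
                 padded_shape = as.integer(padded),
                 pad = list(lead = as.integer(pad_lead),
                            trail = as.integer(pad_trail)),
                 windows = windows),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat(sprintf("<tiling_plan %dx%d image, %d tiles of %d (overlap %d, stride %d)>\n",
              x$shape[1], x$shape[2], nrow(x$windows), x$tile_size,
              x$overlap, x$stride))
  invisible(x)
}

# Reflect-pad an image to the plan's padded shape.
.pad_reflect <- function(img, plan) {
  ri <- .reflect_idx(seq_len(plan$padded_shape[1]) - plan$pad$lead[1], nrow(img))
  ci <- .reflect_idx(seq_len(plan$padded_shape[2]) - plan$pad$lead[2], ncol(img))
  img[ri, ci, drop = FALSE]
}

#' How often each output pixel is written by the plan's central crops
#'
#' Diagnostic for the exactly-once stitching invariant: the returned matrix
#' is all ones for a valid plan.
#' @param plan A `tiling_plan`.
#' @return Integer matrix of the original image shape.
#' @export
tile_coverage <- function(plan) {
  cov <- matrix(0L, plan$shape[1], plan$shape[2])
  half <- plan$overlap / 2
  for (i in seq_len(nrow(plan$windows))) {
    w <- plan$windows[i, ]
    # central crop in padded coords -> original coords
    r <- (w$row0 + half):(w$row0 + half + plan$stride - 1L) - plan$pad$lead[1]
    c <- (w$col0 + half):(w$col0 + half + plan$stride - 1L) - plan$pad$lead[2]
    r <- r[r >= 0 & r < plan$shape[1]]
    c <- c[c >= 0 & c < plan$shape[2]]
    cov[r + 1L, c + 1L] <- cov[r + 1L, c + 1L] + 1L
  }
  cov
}

#' Predict a seven-channel probability map for a whole image
#'
#' Runs the model tile by tile over the plan and stitches the central crops,
#' so each output pixel comes from the tile in whose central region it falls.
#'
#' @param model A `ws_model`, or any function mapping a tile matrix to an
#'   H x W x 7 array (useful for stub models in tests).
#' @param img Numeric image matrix (already normalized).
#' @param plan A `tiling_plan`; defaults to a plan for `img` using the
#'   model's tile size.
#' @param use_best Passed to [predict_model()] for `ws_model`s.
#' @return Prediction-flavor `target_stack` of the image's shape.
#' @export
predict_tiled <- function(model, img, plan = NULL, use_best = FALSE) {
  .stopifnot_matrix(img)
  if (is.null(plan)) {
    ts <- if (inherits(model, "ws_model")) model$spec$input_tile else 256L
    plan <- plan_tiles(dim(img), tile_size = ts,
                       overlap = min(32L, 2L * (ts %/% 8L %/% 2L)))
  }
  if (inherits(model, "ws_model") && model$spec$input_tile != plan$tile_size) {
    stop("model input size (", model$spec$input_tile,
         ") != plan tile size (", plan$tile_size, ")")
  }
  fwd <- if (inherits(model, "ws_model")) {
    function(tile) unclass(predict_model(model, tile, use_best = use_best))
  } else {
    model
  }
  padded <- .pad_reflect(img, plan)
  out <- array(0, dim = c(plan$shape, 7L))
  half <- plan$overlap / 2
  for (i in seq_len(nrow(plan$windows))) {
    w <- plan$windows[i, ]
    tile <- padded[(w$row0 + 1L):w$row1, (w$col0 + 1L):w$col1, drop = FALSE]
    p <- fwd(tile)
    # central crop, clipped to the original image extent
    rr <- (w$row0 + half):(w$row0 + half + plan$stride - 1L) - plan$pad$lead[1]
    cc <- (w$col0 + half):(w$col0 + half + plan$stride - 1L) - plan$pad$lead[2]
    rsel <- rr >= 0 & rr < plan$shape[1]
    csel <- cc >= 0 & cc < plan$shape[2]
    tr <- (half + 1L):(half + plan$stride)
    out[rr[rsel] + 1L, cc[csel] + 1L, ] <- p[tr[rsel], tr[csel], , drop = FALSE]
  }
  target_stack(out, "prediction")
}
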