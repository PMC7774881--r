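# Paired geometric/photometric augmentation: one sampled transform is applied
# identically to the input image and its seven targets. Interpolation is
# bilinear for the intensity image and nearest-neighbour for targets (keeps
# one-pixel boundaries from fattening); out-of-field pixels are filled
# respecting channel polarity (0 for mask/seed channels, 1 for negatives) so
# the target-stack invariants survive any transform.

# per-role out-of-field fill values
.TARGET_FILL <- c(0, 0, 0, 1, 1, 0, 1)

#' Augmentation specification
#'
#' Ranges of the random transform family: rotation (degrees), translation
#' (fraction of the image side, applied per axis), zoom (magnification about
#' the centre), flip probabilities, and multiplicative intensity jitter
#' applied to the input image only.
#'
#' @param rotation Ordered range of rotation angles in degrees.
#' @param translation Ordered range of per-axis translation fractions.
#' @param zoom Ordered range of zoom factors around 1.
#' @param flip_h,flip_v Probabilities of horizontal/vertical flips.
#' @param jitter Ordered range of relative intensity jitter (input only).
#' @param rng_seed Optional integer seed making [sample_transform()] draws
#'   reproducible.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(rotation = c(0, 360), translation = c(-0.1, 0.1),
                         zoom = c(0.8, 1.2), flip_h = 0.5, flip_v = 0.5,
                         jitter = c(-0.1, 0.1), rng_seed = NULL) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop("`", nm, "` must be an ordered pair")
  }
  chk(rotation, "rotation"); chk(translation, "translation")
  chk(zoom, "zoom"); chk(jitter, "jitter")
  stopifnot(flip_h >= 0, flip_h <= 1, flip_v >= 0, flip_v <= 1)
  structure(list(rotation = rotation, translation = translation, zoom = zoom,
                 flip_h = flip_h, flip_v = flip_v, jitter = jitter,
                 rng_seed = rng_seed),
            class = "augment_spec")
}

#' Identity (no-op) augmentation specification
#' @export
identity_augment <- function() {
  augment_spec(rotation = c(0, 0), translation = c(0, 0), zoom = c(1, 1),
               flip_h = 0, flip_v = 0, jitter = c(0, 0))
}

#' Flip/right-angle-only augmentation specification
#'
#' Restricted to transforms that commute exactly with target encoding (no
#' interpolation): flips with probability 1/2 each and rotations by multiples
#' of 90 degrees.
#' @export
orthogonal_augment <- function() {
  structure(list(rotation = c(0, 360), translation = c(0, 0), zoom = c(1, 1),
                 flip_h = 0.5, flip_v = 0.5, jitter = c(0, 0),
                 rng_seed = NULL, right_angles = TRUE),
            class = "augment_spec")
}

#' Draw one concrete transform from an augmentation specification
#'
#' Each parameter is drawn uniformly from its range; flips are Bernoulli.
#' Deterministic given a seed.
#'
#' @param spec An [augment_spec()].
#' @param seed Optional integer seed (defaults to `spec$rng_seed`; `NULL`
#'   draws from the current RNG stream).
#' @return A `sampled_transform` list with concrete values.
#' @export
sample_transform <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "augment_spec"))
  if (!is.null(seed)) set.seed(seed)
  rot <- runif(1, spec$rotation[1], spec$rotation[2])
  if (isTRUE(spec$right_angles)) rot <- 90 * (sample.int(4L, 1L) - 1L)
  structure(list(
    rotation = rot,
    translation = runif(2, spec$translation[1], spec$translation[2]),
    zoom = runif(1, spec$zoom[1], spec$zoom[2]),
    flip_h = runif(1) < spec$flip_h,
    flip_v = runif(1) < spec$flip_v,
    jitter = runif(1, spec$jitter[1], spec$jitter[2])
  ), class = "sampled_transform")
}

# Output->source affine matrix (0-based coordinates) for rotation/zoom about
# the image centre followed by translation; exact at right angles because
# cospi/sinpi are exact on half-integers.
.affine_matrix <- function(t, d) {
  th <- t$rotation / 180
  cs <- cospi(th); sn <- sinpi(th)
  ctr <- (d - 1) / 2
  tr <- t$translation * d
  # forward: dst = R z (src - ctr) + ctr + tr  =>  src = R^-1 (dst-ctr-tr)/z + ctr
  a <- cs / t$zoom; b <- sn / t$zoom
  # R^-1 = [cs sn; -sn cs] for rotation by th of (row, col)
  c(a, b, -a * (ctr[1] + tr[1]) - b * (ctr[2] + tr[2]) + ctr[1],
    -b, a, b * (ctr[1] + tr[1]) - a * (ctr[2] + tr[2]) + ctr[2])
}

.apply_flips <- function(m, t) {
  if (t$flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (t$flip_v) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Apply one sampled transform to an image and its seven targets
#'
#' The geometric part (rotation, zoom, translation, flips) is applied
#' identically to all eight planes; intensity jitter only touches the input.
#' Targets are resampled nearest-neighbour and re-binarized, with per-role
#' out-of-field fills, so all target-stack invariants still hold afterwards.
#'
#' @param t A `sampled_transform`.
#' @param img Numeric intensity matrix.
#' @param targets Target-flavor `target_stack` of matching shape.
#' @return `list(image =, targets =)`.
#' @export
apply_paired <- function(t, img, targets) {
  stopifnot(inherits(t, "sampled_transform"), inherits(targets, "target_stack"))
  if (!all(dim(img) == dim(targets)[1:2])) stop("image/targets shape mismatch")
  M <- .affine_matrix(t, dim(img))
  out_img <- .affine_sample(img, M, TRUE, 0)
  out_img <- .apply_flips(out_img, t)
  out_img <- .clip01(out_img * (1 + t$jitter))
  arr <- array(0, dim = dim(targets))
  for (k in 1:7) {
    ch <- .affine_sample(matrix(targets[, , k], dim(img)[1], dim(img)[2]),
                         M, FALSE, .TARGET_FILL[k])
    arr[, , k] <- round(.apply_flips(ch, t))
  }
  list(image = out_img, targets = target_stack(arr, "target"))
}
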