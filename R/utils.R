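# Internal helpers shared across modules.

# EBImage wrappers: keep plain base matrices at module boundaries.
.ebi <- function(m) EBImage::Image(m)

.brush3 <- function() matrix(1L, 3L, 3L)

.dilate3 <- function(m) {
  EBImage::imageData(EBImage::dilate(.ebi(m * 1), .brush3())) > 0.5
}

.erode3 <- function(m) {
  EBImage::imageData(EBImage::erode(.ebi(m * 1), .brush3())) > 0.5
}

# Euclidean distance, for each TRUE pixel of `m`, to the nearest FALSE pixel;
# the image border is treated as FALSE (distances are computed on a 0-padded
# copy), so objects touching the frame stay finite.
.distmap_padded <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m * 1
  d <- EBImage::imageData(EBImage::distmap(.ebi(p)))
  d[2:(nr + 1L), 2:(nc + 1L)]
}

# Euclidean distance to the nearest TRUE pixel of `m` (no border effect).
.dist_to_set <- function(m) {
  if (!any(m)) stop("distance to an empty set is undefined")
  d <- EBImage::imageData(EBImage::distmap(.ebi(1 - m * 1)))
  d
}

.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(.ebi(m), sigma = sigma))
}

.clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

.is_binary <- function(m) all(m %in% c(0, 1) | is.logical(m))

# Mirror (reflect) index for out-of-range coordinates, 1-based, without edge
# repetition; period 2n - 2 so arbitrarily large pads fold back correctly.
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j >= n, 2L * n - 2L - j, j)
  j + 1L
}

.stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(sprintf("`%s` must be a 2D matrix", name))
}
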