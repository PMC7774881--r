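# Shared fixtures: all built in code at test time.

# A clean synthetic tissue (canonical ground truth + membrane image).
make_tissue <- function(seed, field = 128L, ...) {
  generate_tissue(tissue_params(field = c(field, field), rng_seed = seed, ...))
}

# Small hand-built label image: a 2x2 grid of square cells separated by a
# one-pixel cross (plus nothing at the frame: border closes virtually).
grid_labels <- function(cell = 16L) {
  n <- 2L * cell + 1L
  L <- matrix(0L, n, n)
  L[1:cell, 1:cell] <- 1L
  L[1:cell, (cell + 2L):n] <- 2L
  L[(cell + 2L):n, 1:cell] <- 3L
  L[(cell + 2L):n, (cell + 2L):n] <- 4L
  L
}

# Independent flooding oracle: process pixels in ascending height; a pixel
# with no previously-processed (i.e. lower) labelled 4-neighbour opens a new
# basin, otherwise it joins the basin of its lowest processed neighbour.
# Basin count = regional-minimum count; no watershed lines are drawn.
# Deliberately a different algorithm from the package's priority-queue
# flooding.
oracle_watershed <- function(h) {
  nr <- nrow(h); nc <- ncol(h); n <- nr * nc
  lab <- integer(n)
  ord <- order(as.vector(h), seq_len(n))
  nreg <- 0L
  for (i in ord) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    nbs <- c(if (r > 1) i - 1L, if (r < nr) i + 1L,
             if (c > 1) i - nr, if (c < nc) i + nr)
    nbs <- nbs[lab[nbs] > 0L]
    if (length(nbs) == 0L) {
      nreg <- nreg + 1L
      lab[i] <- nreg
    } else {
      lab[i] <- lab[nbs[which.min(h[nbs])]]
    }
  }
  list(labels = matrix(lab, nr, nc), n_regions = nreg)
}

# Brute-force SEG: literal double loop over every (gt, pred) cell pair.
oracle_seg <- function(gt, pred) {
  gl <- setdiff(unique(as.vector(gt)), 0L)
  pl <- setdiff(unique(as.vector(pred)), 0L)
  total <- 0
  for (g in gl) {
    R <- which(gt == g)
    best <- 0
    for (p in pl) {
      S <- which(pred == p)
      ov <- length(intersect(R, S))
      if (ov > 0.5 * length(R)) best <- ov / length(union(R, S))
    }
    total <- total + best
  }
  total / length(gl)
}

# Brute-force AP: exhaustive search over one-to-one matchings maximizing the
# number of pairs with IoU >= thr.
oracle_ap <- function(gt, pred, thr = 0.7) {
  gl <- setdiff(unique(as.vector(gt)), 0L)
  pl <- setdiff(unique(as.vector(pred)), 0L)
  pairs <- list()
  for (g in gl) for (p in pl) {
    R <- which(gt == g); S <- which(pred == p)
    v <- length(intersect(R, S)) / length(union(R, S))
    if (v >= thr) pairs[[length(pairs) + 1L]] <- c(g, p)
  }
  best_tp <- 0L
  rec <- function(k, used_g, used_p, tp) {
    if (tp + (length(pairs) - k + 1L) <= best_tp) return()
    if (k > length(pairs)) { best_tp <<- max(best_tp, tp); return() }
    pr <- pairs[[k]]
    if (!(pr[1] %in% used_g) && !(pr[2] %in% used_p)) {
      rec(k + 1L, c(used_g, pr[1]), c(used_p, pr[2]), tp + 1L)
    }
    rec(k + 1L, used_g, used_p, tp)
  }
  rec(1L, integer(), integer(), 0L)
  tp <- best_tp
  fp <- length(pl) - tp; fn <- length(gl) - tp
  if (tp + fp + fn == 0L) return(list(tp = 0L, fp = 0L, fn = 0L, ap = 1))
  list(tp = tp, fp = fp, fn = fn, ap = tp / (tp + fp + fn))
}

# Random small label image (<= ~8 cells) plus a perturbed prediction:
# translated, with occasional merges and drops.
perturbed_pair <- function(seed) {
  set.seed(seed)
  smp <- generate_tissue(tissue_params(field = c(32L, 32L), density = 60,
                                       psf_sigma = 0, noise_sd = 0,
                                       gradient_amplitude = 0,
                                       lloyd_iters = 1L, rng_seed = seed))
  gt <- smp$truth
  pred <- gt
  dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
  nr <- nrow(gt); nc <- ncol(gt)
  shifted <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  shifted[rs, cs] <- pred[rs - dr, cs - dc]
  pred <- shifted
  labs <- setdiff(unique(as.vector(pred)), 0L)
  if (length(labs) >= 2 && runif(1) < 0.5) {
    m <- sample(labs, 2); pred[pred == m[1]] <- m[2]   # merge
  }
  if (length(labs) >= 1 && runif(1) < 0.3) {
    pred[pred == sample(labs, 1)] <- 0L                # drop
  }
  list(gt = gt, pred = pred)
}
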