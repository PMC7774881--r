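# LinkNet-style encoder-decoder on a compact CPU convolution stack.
#
# Five VGG-style encoder stages (stacked 3x3 conv + instance norm + ReLU,
# 2x2 max-pool) mirrored by five decoder stages (nearest 2x upsample, 3x3
# conv + instance norm + ReLU, additive skip from the matching encoder
# stage), a 3x3 + 1x1 head and a sigmoid bounding the seven output channels
# to [0, 1]. Instance normalization (per-sample, per-channel) takes the role
# batch norm plays in standard LinkNet decoders: without it, a from-scratch
# network trained with the pure Jaccard loss collapses into the saturated
# all-ones local optimum. Layers, the Adam optimizer and the soft Jaccard
# loss are implemented in this package (src/convnet.cpp does the heavy
# lifting); the paper-scale preset uses the published hyperparameters, a
# `tiny` preset keeps CPU training tractable.

.BASE_WIDTHS <- c(64, 128, 256, 512, 512)

#' Model specification
#'
#' @param architecture Only `"linknet"` (encoder-decoder with additive
#'   skips).
#' @param encoder `"vgg16_style"` (conv counts 2,2,3,3,3 per stage) or
#'   `"tiny"` (1,1,2,2,2; the test-suite workhorse).
#' @param input_tile Square input tile side; must be divisible by 32 (five
#'   2x downsamplings).
#' @param width_multiplier Multiplier in (0, 1] on the VGG16 stage widths
#'   (64, 128, 256, 512, 512).
#' @param out_channels Fixed at 7.
#' @return A `model_spec` list.
#' @export
model_spec <- function(architecture = "linknet",
                       encoder = c("vgg16_style", "tiny"),
                       input_tile = 256L, width_multiplier = 1,
                       out_channels = 7L) {
  encoder <- match.arg(encoder)
  architecture <- match.arg(architecture, "linknet")
  if (input_tile %% 32L != 0L) {
    stop("input_tile must be divisible by 32 (encoder downsampling depth)")
  }
  stopifnot(width_multiplier > 0, width_multiplier <= 1, out_channels == 7L)
  widths <- pmax(1L, as.integer(round(.BASE_WIDTHS * width_multiplier)))
  convs <- if (encoder == "vgg16_style") c(2L, 2L, 3L, 3L, 3L) else c(1L, 1L, 2L, 2L, 2L)
  structure(list(architecture = architecture, encoder = encoder,
                 input_tile = as.integer(input_tile),
                 width_multiplier = width_multiplier,
                 out_channels = as.integer(out_channels),
                 widths = widths, convs = convs),
            class = "model_spec")
}

#' Tiny CPU preset of the model specification
#' @param input_tile Tile side (default 64).
#' @export
tiny_model_spec <- function(input_tile = 64L) {
  model_spec(encoder = "tiny", input_tile = input_tile, width_multiplier = 0.125)
}

.he_init <- function(fan_in, n_out, k) {
  matrix(rnorm(k * k * fan_in * n_out, sd = sqrt(2 / (k * k * fan_in))),
         nrow = k * k * fan_in, ncol = n_out)
}

# conv + instance-norm parameter leaf
.conv_in_params <- function(fan_in, n_out, k) {
  list(w = .he_init(fan_in, n_out, k), b = numeric(n_out),
       g = rep(1, n_out), bt = numeric(n_out))
}

# Instance normalization: each channel of one sample is standardized over
# its H x W extent, then scaled/shifted by learnable (g, bt).
.in_fw <- function(x, g, bt) {
  d <- dim(x)
  xhat <- array(0, d)
  sdv <- numeric(d[3])
  for (k in seq_len(d[3])) {
    v <- x[, , k]
    mu <- mean(v)
    sdv[k] <- sqrt(mean((v - mu)^2) + 1e-5)
    xhat[, , k] <- (v - mu) / sdv[k]
  }
  y <- xhat
  for (k in seq_len(d[3])) y[, , k] <- g[k] * xhat[, , k] + bt[k]
  list(y = y, xhat = xhat, sd = sdv)
}

.in_bw <- function(dy, g, cache) {
  d <- dim(dy)
  dx <- array(0, d)
  dg <- numeric(d[3]); dbt <- numeric(d[3])
  for (k in seq_len(d[3])) {
    xh <- cache$xhat[, , k]
    dyk <- dy[, , k]
    dg[k] <- sum(dyk * xh)
    dbt[k] <- sum(dyk)
    dxh <- dyk * g[k]
    dx[, , k] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / cache$sd[k]
  }
  list(dx = dx, dg = dg, dbt = dbt)
}

#' Build an (untrained) model
#'
#' Weights use He-normal initialization from the current R RNG; pass
#' `rng_seed` for reproducible builds. No pretrained weights are involved.
#'
#' @param spec A [model_spec()].
#' @param rng_seed Optional integer seed.
#' @return A `ws_model` with empty training history.
#' @export
build_model <- function(spec = model_spec(), rng_seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  w <- spec$widths
  params <- list(enc = vector("list", 5L), dec = vector("list", 5L))
  cin <- 1L
  for (s in 1:5) {
    stage <- vector("list", spec$convs[s])
    for (j in seq_len(spec$convs[s])) {
      stage[[j]] <- .conv_in_params(cin, w[s], 3L)
      cin <- w[s]
    }
    params$enc[[s]] <- stage
  }
  # decoder stage s emits the width of encoder stage s (so the additive skip
  # matches); it consumes the previous decoder stage's width (w5 at the top)
  for (s in 5:1) {
    din <- if (s == 5L) w[5] else w[s + 1]
    params$dec[[s]] <- .conv_in_params(din, w[s], 3L)
  }
  params$head3 <- .conv_in_params(w[1], w[1], 3L)
  params$head1 <- list(w = .he_init(w[1], spec$out_channels, 1L),
                       b = numeric(spec$out_channels))
  structure(list(spec = spec, params = params, history = NULL),
            class = "ws_model")
}

#' @export
print.ws_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<ws_model %s/%s tile %d, %d parameters, %s>\n",
              x$spec$architecture, x$spec$encoder, x$spec$input_tile, np,
              if (is.null(x$history)) "untrained" else
                sprintf("%d epochs trained", max(x$history$epoch))))
  invisible(x)
}

.relu <- function(x) { x[x < 0] <- 0; x }

# conv + instance norm + relu block, forward
.block_fw <- function(x, p) {
  pre <- .conv2d_fw(x, p$w, p$b, 3L)
  inn <- .in_fw(pre, p$g, p$bt)
  list(a = .relu(inn$y), xin = x, inn = inn)
}

# ... and backward: returns list(grads, dx)
.block_bw <- function(p, cache, d_a) {
  dnorm <- d_a * (cache$inn$y > 0)
  ib <- .in_bw(dnorm, p$g, cache$inn)
  bw <- .conv2d_bw(cache$xin, p$w, ib$dx, 3L)
  list(g = list(w = bw$dw, b = bw$db, g = ib$dg, bt = ib$dbt), dx = bw$dx)
}

# Forward pass. x: H x W matrix. Returns list(y, cache) when cache = TRUE.
.net_forward <- function(params, spec, x, cache = FALSE) {
  a <- array(x, dim = c(dim(x), 1L))
  cc <- if (cache) list(enc = vector("list", 5L), pool = vector("list", 5L),
                        dec = vector("list", 5L)) else NULL
  skips <- vector("list", 5L)
  for (s in 1:5) {
    st <- params$enc[[s]]
    if (cache) cc$enc[[s]] <- vector("list", length(st))
    for (j in seq_along(st)) {
      blk <- .block_fw(a, st[[j]])
      a <- blk$a
      if (cache) cc$enc[[s]][[j]] <- blk
    }
    skips[[s]] <- a
    mp <- .maxpool2_fw(a)
    if (cache) cc$pool[[s]] <- mp
    a <- mp$y
  }
  for (s in 5:1) {
    up <- .upsample2_fw(a)
    blk <- .block_fw(up, params$dec[[s]])
    a <- blk$a + skips[[s]]
    if (cache) cc$dec[[s]] <- blk
  }
  h3 <- .block_fw(a, params$head3)
  z <- .conv2d_fw(h3$a, params$head1$w, params$head1$b, 1L)
  # clamp away from exact 0/1 so saturated pixels keep a live gradient
  y <- pmin(pmax(1 / (1 + exp(-z)), 1e-7), 1 - 1e-7)
  if (cache) {
    cc$h3 <- h3; cc$y <- y
    cc$skips <- skips
  }
  list(y = y, cache = cc)
}

# Backward pass: dy is dLoss/dy (post-sigmoid). Returns gradients shaped like
# params.
.net_backward <- function(params, spec, cc, dy) {
  g <- list(enc = vector("list", 5L), dec = vector("list", 5L))
  dz <- dy * cc$y * (1 - cc$y)
  bw <- .conv2d_bw(cc$h3$a, params$head1$w, dz, 1L)
  g$head1 <- list(w = bw$dw, b = bw$db)
  hb <- .block_bw(params$head3, cc$h3, bw$dx)
  g$head3 <- hb$g
  d_a <- hb$dx  # gradient wrt decoder stage-1 output
  dskips <- vector("list", 5L)
  for (s in 1:5) {
    # d_a = grad wrt (act + skip_s): split between the block and the skip
    dskips[[s]] <- d_a
    db <- .block_bw(params$dec[[s]], cc$dec[[s]], d_a)
    g$dec[[s]] <- db$g
    d_a <- .upsample2_bw(db$dx)  # grad wrt pooled output of stage s
  }
  # d_a now holds grad wrt pool-5 output; walk the encoder backwards
  for (s in 5:1) {
    mp <- cc$pool[[s]]
    d_post <- .maxpool2_bw(d_a, mp$amax, mp$H, mp$W) + dskips[[s]]
    st <- params$enc[[s]]
    g$enc[[s]] <- vector("list", length(st))
    for (j in rev(seq_along(st))) {
      eb <- .block_bw(st[[j]], cc$enc[[s]][[j]], d_post)
      g$enc[[s]][[j]] <- eb$g
      d_post <- eb$dx
    }
    d_a <- d_post  # grad wrt input of stage s = pooled output of stage s-1
  }
  g
}

#' Soft Jaccard (IoU) loss
#'
#' Per channel c, `J_c = (sum(y yhat) + eps) / (sum(y) + sum(yhat) -
#' sum(y yhat) + eps)`; the loss is `1 - mean_c(J_c)` (default) or the same
#' expression on the flattened 7-channel tensor (`per_channel = FALSE`).
#' Bounded to \[0, 1); identical binary inputs give a loss of order
#' `1/(n + eps)`.
#'
#' @param y_true,y_pred H x W x 7 arrays (targets binary, predictions in
#'   \[0, 1\]).
#' @param eps Smoothing constant (default 1, stabilizes empty channels).
#' @param per_channel Average the per-channel Jaccard indices (default) or
#'   compute one index over the flattened tensor.
#' @return Scalar loss.
#' @export
jaccard_loss <- function(y_true, y_pred, eps = 1, per_channel = TRUE) {
  stopifnot(all(dim(y_true) == dim(y_pred)), eps > 0)
  .jaccard(y_true, y_pred, eps, per_channel, grad = FALSE)$loss
}

.jaccard <- function(y_true, y_pred, eps, per_channel = TRUE, grad = TRUE) {
  if (per_channel) {
    nch <- dim(y_true)[3]
    J <- numeric(nch)
    dpred <- if (grad) array(0, dim(y_true)) else NULL
    for (k in seq_len(nch)) {
      yt <- y_true[, , k]; yp <- y_pred[, , k]
      I <- sum(yt * yp); U <- sum(yt) + sum(yp) - I
      J[k] <- (I + eps) / (U + eps)
      if (grad) {
        dpred[, , k] <- -(yt * (U + eps) - (I + eps) * (1 - yt)) /
          ((U + eps)^2 * nch)
      }
    }
    list(loss = 1 - mean(J), dpred = dpred)
  } else {
    I <- sum(y_true * y_pred); U <- sum(y_true) + sum(y_pred) - I
    dpred <- if (grad) {
      -(y_true * (U + eps) - (I + eps) * (1 - y_true)) / (U + eps)^2
    } else NULL
    list(loss = 1 - (I + eps) / (U + eps), dpred = dpred)
  }
}

#' Training configuration
#'
#' Defaults are the published schedule: 300 epochs of Adam at learning rate
#' 1e-3 for the first 150 epochs, then 1e-4, batch size 24.
#'
#' @param epochs Number of full passes over the dataset.
#' @param batch_size Samples per optimizer step.
#' @param lr_phase1,lr_phase2 Learning rates of the two phases.
#' @param phase_split_epoch Last epoch of phase 1 (must not exceed `epochs`).
#' @param optimizer Only `"adam"`.
#' @param rng_seed Integer seed driving shuffling, augmentation and any other
#'   randomness in the loop.
#' @param augment `NULL` (off) or an [augment_spec()] applied per sample.
#' @param eps Jaccard smoothing constant.
#' @param per_channel Loss reduction mode, see [jaccard_loss()].
#' @param holdout_frac Optional fraction of the dataset held out of the
#'   optimizer (default 0: train on everything every epoch, checkpoint on
#'   training loss). When positive, the holdout loss is logged per epoch and
#'   drives the best-weights checkpoint.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 24L, lr_phase1 = 1e-3,
                         lr_phase2 = 1e-4, phase_split_epoch = 150L,
                         optimizer = "adam", rng_seed = 1L, augment = NULL,
                         eps = 1, per_channel = TRUE, holdout_frac = 0) {
  optimizer <- match.arg(optimizer, "adam")
  if (phase_split_epoch > epochs) stop("phase_split_epoch must be <= epochs")
  stopifnot(epochs >= 1, batch_size >= 1, lr_phase1 > 0, lr_phase2 > 0,
            holdout_frac >= 0, holdout_frac < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 phase_split_epoch = as.integer(phase_split_epoch),
                 optimizer = optimizer, rng_seed = as.integer(rng_seed),
                 augment = augment, eps = eps, per_channel = per_channel,
                 holdout_frac = holdout_frac),
            class = "train_config")
}

#' Learning rate of the two-phase schedule at a given epoch
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  ifelse(epoch <= cfg$phase_split_epoch, cfg$lr_phase1, cfg$lr_phase2)
}

# elementwise update over a params-shaped nested list (match by name where
# names exist: gradient containers may order their fields differently); `f`
# acts on each numeric field of a parameter leaf
.map2_params <- function(a, b, f) {
  if (is.list(a) && !is.null(a$w)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
    return(out)
  }
  out <- a
  keys <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (k in keys) out[[k]] <- .map2_params(a[[k]], b[[k]], f)
  out
}

.zeros_like <- function(p) {
  if (is.list(p) && !is.null(p$w)) return(lapply(p, function(x) x * 0))
  lapply(p, .zeros_like)
}

#' Train a model
#'
#' Runs `cfg$epochs` full passes with Adam and the two-phase learning-rate
#' schedule, applying the paired augmentation (if configured) per sample.
#' Keeps a checkpoint of the best-epoch weights (lowest mean training loss)
#' and records the per-epoch history. Deterministic for a fixed
#' `cfg$rng_seed`.
#'
#' @param model A `ws_model` from [build_model()].
#' @param dataset Non-empty list of samples, each `list(x = tile matrix,
#'   y = target-flavor target_stack / array)` of side `spec$input_tile`.
#' @param cfg A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The trained `ws_model`; `$history` is a data.frame (epoch, lr,
#'   loss) and `$best` holds the checkpointed weights and epoch.
#' @export
train_model <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "ws_model"), inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("training dataset is empty")
  tile <- model$spec$input_tile
  for (s in dataset) {
    if (!all(dim(s$x) == c(tile, tile))) {
      stop("all tiles must match spec$input_tile = ", tile)
    }
  }
  set.seed(cfg$rng_seed)
  holdout <- list()
  if (cfg$holdout_frac > 0) {
    nh <- max(1L, floor(cfg$holdout_frac * length(dataset)))
    hi <- sample.int(length(dataset), nh)
    holdout <- dataset[hi]
    dataset <- dataset[-hi]
    if (length(dataset) == 0L) stop("holdout fraction leaves no training data")
  }
  params <- model$params
  m_st <- .zeros_like(params); v_st <- .zeros_like(params)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8; step <- 0L
  n <- length(dataset)
  hist <- NULL
  epoch0 <- if (is.null(model$history)) 0L else max(model$history$epoch)
  best <- list(loss = Inf, params = params, epoch = 0L)

  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      gacc <- NULL
      for (i in idx) {
        smp <- dataset[[i]]
        x <- smp$x; y <- smp$y
        if (!is.null(cfg$augment)) {
          tr <- sample_transform(cfg$augment, seed = NULL)
          ts <- if (inherits(y, "target_stack")) y else target_stack(y, "target")
          aug <- apply_paired(tr, x, ts)
          x <- aug$image; y <- aug$targets
        }
        fw <- .net_forward(params, model$spec, x, cache = TRUE)
        jl <- .jaccard(unclass(y), fw$y, cfg$eps, cfg$per_channel)
        if (!is.finite(jl$loss)) {
          stop("training aborted: loss became non-finite at epoch ", ep)
        }
        losses <- c(losses, jl$loss)
        g <- .net_backward(params, model$spec, fw$cache, jl$dpred)
        gacc <- if (is.null(gacc)) g else {
          .map2_params(gacc, g, function(a, b) a + b)
        }
      }
      sc <- 1 / length(idx)
      step <- step + 1L
      m_st <- .map2_params(m_st, gacc, function(m, g) b1 * m + (1 - b1) * g * sc)
      v_st <- .map2_params(v_st, gacc, function(v, g) b2 * v + (1 - b2) * (g * sc)^2)
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      upd <- .map2_params(m_st, v_st, function(m, v) (m / c1) / (sqrt(v / c2) + aeps))
      params <- .map2_params(params, upd, function(p, u) p - lr * u)
    }
    mloss <- mean(losses)
    vloss <- NA_real_
    if (length(holdout)) {
      vloss <- mean(vapply(holdout, function(smp) {
        .jaccard(unclass(smp$y), .net_forward(params, model$spec, smp$x)$y,
                 cfg$eps, cfg$per_channel, grad = FALSE)$loss
      }, numeric(1)))
    }
    hist <- rbind(hist, data.frame(epoch = epoch0 + ep, lr = lr, loss = mloss,
                                   holdout_loss = vloss))
    crit <- if (length(holdout)) vloss else mloss
    if (crit < best$loss) best <- list(loss = crit, params = params,
                                       epoch = epoch0 + ep)
    if (verbose) {
      message(sprintf("epoch %d lr %.1e loss %.5f%s", epoch0 + ep, lr, mloss,
                      if (length(holdout)) sprintf(" holdout %.5f", vloss) else ""))
    }
  }
  model$params <- params
  model$history <- rbind(model$history, hist)
  model$best <- best
  model
}

#' Predict the seven-channel probability stack for one tile
#'
#' @param model A `ws_model`.
#' @param x Tile matrix of side `spec$input_tile` (any same-shape matrix
#'   works for the fully convolutional net as long as both sides are
#'   divisible by 32).
#' @param use_best Use the checkpointed best-loss weights when available.
#' @return Prediction-flavor `target_stack`.
#' @export
predict_model <- function(model, x, use_best = FALSE) {
  stopifnot(inherits(model, "ws_model"))
  p <- if (use_best && !is.null(model$best)) model$best$params else model$params
  target_stack(.net_forward(p, model$spec, x)$y, "prediction")
}

#' Save / load a trained model
#'
#' Weights go to `path` in R's native serialization; a human-readable JSON
#' sidecar (`<path>.json`) records the model specification and training
#' history.
#' @param model A `ws_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ws_model"))
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec),
               history = model$history,
               best_epoch = if (!is.null(model$best)) model$best$epoch else NULL)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ws_model"))
  m
}
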