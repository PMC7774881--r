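test_that("the model forward pass has the contracted shape and range", {
  spec <- model_spec(encoder = "tiny", input_tile = 64L,
                     width_multiplier = 0.125)
  m <- build_model(spec, rng_seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- predict_model(m, x)
  expect_equal(dim(y), c(64L, 64L, 7L))
  expect_true(all(y >= 0 & y <= 1))
  expect_identical(attr(y, "flavor"), "prediction")
  # paper-scale spec accepts 256 tiles (shape check only: run the tiny net
  # fully convolutionally on a 256 tile)
  y256 <- predict_model(m, matrix(0.5, 256, 256))
  expect_equal(dim(y256), c(256L, 256L, 7L))
  expect_error(model_spec(input_tile = 100L), "divisible by 32")
  expect_silent(model_spec(input_tile = 256L))
})

test_that("builds and training runs are deterministic under a fixed seed", {
  spec <- model_spec(encoder = "tiny", input_tile = 32L,
                     width_multiplier = 0.0625)
  x <- matrix(runif(32 * 32), 32, 32)
  m1 <- build_model(spec, rng_seed = 9)
  m2 <- build_model(spec, rng_seed = 9)
  expect_identical(predict_model(m1, x), predict_model(m2, x))

  smp <- make_tissue(1, 32L)
  tiles <- list(list(x = smp$image, y = encode_targets(smp$truth)))
  # augmented epochs included: the whole loop must be bit-reproducible
  cfg <- train_config(epochs = 3, batch_size = 1, phase_split_epoch = 2,
                      rng_seed = 4, lr_phase1 = 1e-4, lr_phase2 = 1e-5,
                      augment = orthogonal_augment())
  h1 <- train_model(m1, tiles, cfg)$history
  h2 <- train_model(m2, tiles, cfg)$history
  expect_identical(h1, h2)
})

test_that("the soft Jaccard loss matches hand arithmetic and bounds", {
  # identical binary input -> loss limited only by eps
  y <- array(0, dim = c(10, 10, 7)); y[3:6, 3:6, ] <- 1
  expect_lt(jaccard_loss(y, y, eps = 1), 1e-6)
  # full complement on dense masks -> loss near 1
  expect_gt(jaccard_loss(y, 1 - y, eps = 1e-6), 0.98)
  # 100 positives, flat 0.5 prediction on a 100-px channel:
  # J = 50 / (100 + 50 - 50) = 0.5
  yt <- array(1, dim = c(10, 10, 1))
  yp <- array(0.5, dim = c(10, 10, 1))
  I <- sum(yt * yp); U <- sum(yt) + sum(yp) - I
  expect_equal(I / U, 0.5)
  expect_equal(jaccard_loss(yt, yp, eps = 1e-12), 0.5, tolerance = 1e-10)
})

test_that("jaccard_loss is 1 - iou on binary masks as eps -> 0", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(runif(16 * 16) < 0.3, 16, 16)
    b <- matrix(runif(16 * 16) < 0.3, 16, 16)
    if (!any(a) && !any(b)) next
    ya <- array(a * 1, dim = c(16, 16, 1))
    yb <- array(b * 1, dim = c(16, 16, 1))
    expect_equal(jaccard_loss(ya, yb, eps = 1e-9), 1 - iou(a, b),
                 tolerance = 1e-6)
  }
})

test_that("training descends, logs the two-phase schedule, and validates", {
  smp <- make_tissue(2, 64L)
  tg <- encode_targets(smp$truth)
  tiles <- lapply(list(c(0, 0), c(0, 32), c(32, 0), c(32, 32)), function(o) {
    rs <- (o[1] + 1):(o[1] + 32); cs <- (o[2] + 1):(o[2] + 32)
    list(x = smp$image[rs, cs],
         y = target_stack(unclass(tg)[rs, cs, , drop = FALSE], "target"))
  })
  spec <- model_spec(encoder = "tiny", input_tile = 32L,
                     width_multiplier = 0.0625)
  m <- build_model(spec, rng_seed = 2)
  cfg <- train_config(epochs = 8, batch_size = 4, phase_split_epoch = 5,
                      lr_phase1 = 3e-4, lr_phase2 = 3e-5, rng_seed = 2)
  m <- train_model(m, tiles, cfg)
  h <- m$history
  expect_lt(tail(h$loss, 1), h$loss[1])
  expect_equal(h$lr, ifelse(h$epoch <= 5, 3e-4, 3e-5))
  expect_equal(m$best$loss, min(h$loss))
  expect_error(train_model(m, list(), cfg), "empty")
  expect_error(train_config(epochs = 10, phase_split_epoch = 20),
               "phase_split_epoch")

  # optional holdout: logged per epoch and drives the checkpoint
  cfg_h <- train_config(epochs = 3, batch_size = 2, phase_split_epoch = 2,
                        lr_phase1 = 3e-4, lr_phase2 = 3e-5, rng_seed = 5,
                        holdout_frac = 0.25)
  mh <- train_model(build_model(spec, rng_seed = 2), tiles, cfg_h)
  expect_true(all(is.finite(mh$history$holdout_loss)))
  expect_equal(mh$best$loss, min(mh$history$holdout_loss))
})

test_that("models round-trip through the checkpoint format", {
  d <- withr::local_tempdir()
  m <- build_model(tiny_model_spec(32L), rng_seed = 3)
  f <- file.path(d, "model.rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_model(f)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_model(m, x), predict_model(m2, x))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$spec$input_tile, 32L)
})
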