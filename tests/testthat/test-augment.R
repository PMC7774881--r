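test_that("sampled transforms are deterministic and respect their ranges", {
  spec <- augment_spec(rng_seed = 5L)
  t1 <- sample_transform(spec)
  t2 <- sample_transform(spec)
  expect_identical(t1, t2)
  # degenerate ranges pin the transform exactly
  spec0 <- augment_spec(rotation = c(33, 33), translation = c(0.02, 0.02),
                        zoom = c(1.1, 1.1), flip_h = 0, flip_v = 1,
                        jitter = c(0.05, 0.05))
  t0 <- sample_transform(spec0, seed = 1)
  expect_equal(t0$rotation, 33)
  expect_equal(t0$translation, c(0.02, 0.02))
  expect_equal(t0$zoom, 1.1)
  expect_false(t0$flip_h); expect_true(t0$flip_v)
  expect_equal(t0$jitter, 0.05)
})

test_that("rotation draws are uniform over the configured range", {
  spec <- augment_spec()
  set.seed(77)
  rots <- vapply(1:10000, function(i) sample_transform(spec, seed = NULL)$rotation,
                 numeric(1))
  se <- 360 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(rots) - 180), 3 * se)
  expect_true(all(rots >= 0 & rots < 360))
})

test_that("the identity transform is a no-op", {
  smp <- make_tissue(3, 64L)
  tg <- encode_targets(smp$truth)
  t0 <- sample_transform(identity_augment(), seed = 1)
  out <- apply_paired(t0, smp$image, tg)
  expect_equal(out$image, smp$image, ignore_attr = TRUE)
  expect_equal(unclass(out$targets), unclass(tg), ignore_attr = TRUE)
})

test_that("flips and quarter-turns commute exactly with target encoding", {
  flip_l <- function(L, t) {
    if (t$flip_h) L <- L[, ncol(L):1, drop = FALSE]
    if (t$flip_v) L <- L[nrow(L):1, , drop = FALSE]
    L
  }
  rot90_l <- function(L) t(L[nrow(L):1, , drop = FALSE])
  for (sd in c(2, 11)) {
    smp <- make_tissue(sd, 64L)
    L <- smp$truth
    tg <- encode_targets(L)
    # flips, through apply_paired
    for (fh in c(TRUE, FALSE)) for (fv in c(TRUE, FALSE)) {
      tr <- structure(list(rotation = 0, translation = c(0, 0), zoom = 1,
                           flip_h = fh, flip_v = fv, jitter = 0),
                      class = "sampled_transform")
      got <- apply_paired(tr, smp$image, tg)$targets
      want <- encode_targets(flip_l(L, tr))
      expect_equal(unclass(got), unclass(want), ignore_attr = TRUE)
    }
    # quarter-turn: array rotation of the encoding equals encoding of the
    # rotated labels
    tg90 <- encode_targets(rot90_l(L))
    for (k in 1:7) {
      expect_equal(unname(rot90_l(matrix(tg[, , k], 64, 64))),
                   unname(matrix(tg90[, , k], 64, 64)))
    }
  }
})

test_that("target invariants survive arbitrary sampled transforms", {
  smp <- make_tissue(7, 64L)
  tg <- encode_targets(smp$truth)
  spec <- augment_spec()
  set.seed(123)
  for (i in 1:50) {
    tr <- sample_transform(spec, seed = NULL)
    out <- apply_paired(tr, smp$image, tg)
    a <- unclass(out$targets)
    expect_true(all(a %in% c(0, 1)))
    expect_equal(a[, , 4], 1 - a[, , 2])
    expect_equal(a[, , 5], 1 - a[, , 3])
    expect_equal(a[, , 7], 1 - a[, , 6])
    expect_true(all(a[, , 2] >= a[, , 1]))
    expect_true(all(a[, , 3] >= a[, , 2]))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})
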