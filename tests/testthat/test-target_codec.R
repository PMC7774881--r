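test_that("encoding a 2x2 grid of squares gives the forced channel geometry", {
  L <- grid_labels(16L)
  tg <- encode_targets(L)
  expect_s3_class(tg, "target_stack")
  expect_equal(dim(tg), c(33L, 33L, 7L))
  # channel 1 is the cross
  expect_equal(tg[, , 1] > 0, unname(labels_to_boundary(L)))
  # channel 2 grows it by one pixel each side (3 wide), channel 3 by two
  expect_equal(sum(tg[, , 2]), 3 * 33 * 2 - 9)
  expect_equal(sum(tg[, , 3]), 5 * 33 * 2 - 25)
  # negatives are exact complements
  expect_equal(tg[, , 4], 1 - tg[, , 2])
  expect_equal(tg[, , 5], 1 - tg[, , 3])
  expect_equal(tg[, , 7], 1 - tg[, , 6])
})

test_that("the seven targets satisfy all structural invariants", {
  for (sd in c(3, 14)) {
    smp <- make_tissue(sd, 96L)
    tg <- encode_targets(smp$truth)
    expect_true(all(tg %in% c(0, 1)))
    expect_equal(tg[, , 4], 1 - tg[, , 2])
    expect_equal(tg[, , 5], 1 - tg[, , 3])
    expect_equal(tg[, , 7], 1 - tg[, , 6])
    expect_true(all(tg[, , 2] >= tg[, , 1]))
    expect_true(all(tg[, , 3] >= tg[, , 2]))
    # one seed component per cell, strictly inside, clear of mask_dil2
    expect_equal(max(memseg:::.cc_label(tg[, , 6] > 0, 4L)), max(smp$truth))
    expect_equal(sum(tg[, , 6] * tg[, , 3]), 0)
    expect_true(all(smp$truth[tg[, , 6] > 0] > 0))
    expect_length(attr(tg, "seed_warnings"), 0)
  }
})

test_that("seed radii scale with sqrt(cell area)", {
  # two rectangular cells of areas 100 and 400, c = 0.2 -> radii 2 and 4
  L <- matrix(0L, 40, 32)
  L[2:11, 2:11] <- 1L          # 10 x 10 = 100
  L[16:35, 6:25] <- 2L         # 20 x 20 = 400
  tg <- encode_targets(L, seed_scale = 0.2)
  for (lab in 1:2) {
    seed_px <- which(tg[, , 6] > 0 & L == lab)
    r <- (seed_px - 1) %% 40 + 1; c <- (seed_px - 1) %/% 40 + 1
    rad <- max(1, floor(0.2 * sqrt(sum(L == lab))))
    expect_equal(max(abs(r - mean(range(r)))), rad)
    # a disk of radius rad has the right pixel count
    dd <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    expect_equal(length(seed_px), sum(dd$dr^2 + dd$dc^2 <= rad^2))
  }
  # radii are monotone in area
  set.seed(5)
  areas <- sort(sample(20:2000, 20))
  radii <- pmax(1, floor(0.2 * sqrt(areas)))
  expect_true(all(diff(radii) >= 0))
})

test_that("a cell too small for a clear seed degrades to one pixel", {
  L <- matrix(0L, 24, 24)
  L[2:20, 2:20] <- 1L
  L[22:23, 2:3] <- 2L   # 2x2 cell: entirely inside mask_dil2
  tg <- encode_targets(L)
  expect_equal(max(memseg:::.cc_label(tg[, , 6] > 0, 4L)), 2L)
  expect_equal(sum(tg[, , 6] > 0 & L == 2L), 1)
  expect_equal(attr(tg, "seed_warnings"), 2L)
})

test_that("perfect predictions decode back to the exact source partition", {
  for (sd in 1:3) {
    smp <- make_tissue(sd, 96L)
    L <- smp$truth
    masks <- targets_to_masks(as_prediction(encode_targets(L)))
    B <- labels_to_boundary(L)
    for (k in c(1, 6, 7)) expect_equal(unname(masks[[k]]), unname(B))
    # inversion symmetry: negatives give the same mask as their positives
    expect_equal(masks[[4]], masks[[2]])
    expect_equal(masks[[5]], masks[[3]])
    Lr <- refined_mask_to_labels(fuse_masks(masks))
    expect_identical(unname(Lr), unname(L))
  }
})

test_that("all-zero prediction stacks fall back gracefully", {
  z <- target_stack(array(0, dim = c(32, 32, 7)), "prediction")
  masks <- targets_to_masks(z)
  # channel 6 has no seeds -> fallback; channel 7 inverts to one all-field
  # seed, whose single-region boundary is empty
  expect_equal(attr(masks, "fallbacks"), 6L)
  expect_false(any(masks[[7]]))
  expect_length(masks, 7)
  fused <- fuse_masks(masks)
  expect_equal(dim(fused), c(32L, 32L))
})

test_that("fusion is a strict majority vote with re-closure", {
  smp <- make_tissue(8, 64L)
  B <- labels_to_boundary(smp$truth)
  empty <- matrix(FALSE, 64, 64)
  # unanimity
  expect_equal(unname(fuse_masks(rep(list(B), 7))), unname(B))
  # 4 of 7 (4/7 > 0.5) -> kept; 3 of 7 -> rejected
  expect_equal(unname(fuse_masks(c(rep(list(B), 4), rep(list(empty), 3)))),
               unname(B))
  expect_equal(fuse_masks(c(rep(list(B), 3), rep(list(empty), 4))), empty)
  # permutation invariance with equal weights
  set.seed(2)
  masks <- c(rep(list(B), 4), rep(list(empty), 3))
  for (i in 1:3) {
    expect_equal(fuse_masks(masks[sample(7)]), fuse_masks(masks))
  }
})

test_that("fusion voting is monotone before re-closure", {
  smp <- make_tissue(8, 64L)
  B <- labels_to_boundary(smp$truth)
  empty <- matrix(FALSE, 64, 64)
  masks <- c(rep(list(B), 3), rep(list(empty), 4))
  cfg <- fusion_config()
  vote1 <- Reduce(`+`, lapply(masks, function(m) m * 1)) / 7
  masks[[4]] <- B  # add boundary pixels to one input
  vote2 <- Reduce(`+`, lapply(masks, function(m) m * 1)) / 7
  expect_true(all(vote2 >= vote1))
})

test_that("target stacks survive a 7-page TIFF round-trip", {
  d <- withr::local_tempdir()
  tg <- encode_targets(grid_labels(8L))
  f <- file.path(d, "stack.tif")
  write_targets(f, tg)
  back <- read_targets(f, flavor = "target")
  expect_equal(unclass(back), unclass(tg), ignore_attr = TRUE)
})
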