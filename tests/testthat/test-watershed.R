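test_that("degenerate height maps flood to a single basin", {
  expect_equal(watershed_lines(matrix(3, 16, 16)), matrix(FALSE, 16, 16))
  # one seed -> one label everywhere, no lines
  s <- matrix(FALSE, 16, 16); s[8, 8] <- TRUE
  L <- seeded_watershed(matrix(runif(256), 16, 16), s)
  expect_equal(L, matrix(1L, 16, 16))
  expect_error(seeded_watershed(matrix(0, 4, 4), matrix(FALSE, 4, 4)),
               "at least one seed")
})

test_that("a symmetric double pit splits exactly at the midline", {
  h <- outer(rep(1, 32), pmin((1:32 - 8)^2, (1:32 - 24)^2))
  b <- watershed_lines(h)
  expect_true(all(b[, 16]))
  expect_equal(sum(b), 32)
  expect_equal(max(boundary_to_labels(b)), 2L)
})

test_that("flooding agrees with an independent ascending-order oracle", {
  # two smooth Gaussian pits: both algorithms find the same two basins and
  # nearly the same division (the one-pixel line is ambiguous by convention)
  r <- matrix(1:32, 32, 32); c <- t(r)
  h <- -exp(-((r - 10)^2 + (c - 9)^2) / 40) -
    exp(-((r - 23)^2 + (c - 22)^2) / 40)
  mine <- watershed_lines(h)
  Lm <- boundary_to_labels(mine)
  orc <- oracle_watershed(h)
  expect_equal(max(Lm), orc$n_regions)
  rep2 <- average_precision(Lm, orc$labels, iou_thr = 0.9)
  expect_equal(rep2$ap, 1)
  # random continuous maps: basin counts agree (line placement on chaotic
  # maps is convention-dependent, counts are not)
  set.seed(41)
  for (rep in 1:20) {
    h <- matrix(runif(16 * 16), 16, 16)
    expect_equal(max(boundary_to_labels(watershed_lines(h))),
                 oracle_watershed(h)$n_regions)
  }
})

test_that("seeded flooding of the double-pit map recovers the two basins", {
  r <- matrix(1:32, 32, 32); c <- t(r)
  h <- -exp(-((r - 10)^2 + (c - 9)^2) / 40) -
    exp(-((r - 23)^2 + (c - 22)^2) / 40)
  s <- matrix(FALSE, 32, 32); s[10, 9] <- TRUE; s[23, 22] <- TRUE
  L <- seeded_watershed(h, s)
  expect_equal(sort(unique(as.vector(L))), 0:2)
  expect_equal(L[10, 9], 1L)
  expect_equal(L[23, 22], 2L)
  # the unseeded lines coincide for this two-minimum map
  expect_equal(L == 0L, watershed_lines(h))
})

test_that("region count equals minimum / seed count on random height maps", {
  set.seed(7)
  for (rep in 1:50) {
    h <- matrix(runif(32 * 32), 32, 32)
    if (rep %% 3 == 0) h <- round(h, 1)  # force plateaus
    nmin <- max(memseg:::.regional_minima(h))
    L <- boundary_to_labels(watershed_lines(h))
    expect_equal(max(L), nmin)
  }
  for (rep in 1:50) {
    h <- matrix(runif(32 * 32), 32, 32)
    s <- matrix(FALSE, 32, 32)
    s[cbind(sample(32, 4), sample(32, 4))] <- TRUE
    ns <- max(memseg:::.cc_label(s, 4L))
    L <- seeded_watershed(h, s)
    expect_equal(length(setdiff(unique(as.vector(L)), 0L)), ns)
  }
})

test_that("boundary masks produced by flooding are watershed-canonical", {
  set.seed(13)
  for (rep in 1:10) {
    h <- matrix(runif(32 * 32), 32, 32)
    expect_true(is_canonical_boundary(watershed_lines(h)))
  }
  smp <- make_tissue(5, 64L)
  expect_true(is_canonical_boundary(labels_to_boundary(smp$truth)))
})

test_that("labels <-> boundary round-trip preserves region membership", {
  # forced geometry: 2x2 grid of squares -> cross boundary, 4 labels
  L <- grid_labels(8L)
  b <- labels_to_boundary(L)
  expect_equal(sum(b), 2 * 17 - 1)
  L2 <- boundary_to_labels(b)
  expect_equal(max(L2), 4L)
  expect_true(all(L2[L > 0] == L[L > 0]))
  # random synthetic tissue: identical membership sets
  smp <- make_tissue(2, 96L)
  L <- smp$truth
  L2 <- boundary_to_labels(labels_to_boundary(L))
  expect_identical(unname(L2), unname(L))
  # single cell filling the frame
  one <- matrix(1L, 10, 10)
  expect_equal(labels_to_boundary(one), matrix(FALSE, 10, 10))
  ring <- labels_to_boundary(one, close_border = TRUE)
  expect_true(all(ring[1, ]) && all(ring[, 1]))
  expect_equal(sum(!ring), 64)
})

test_that("seeded flooding of the negated distance map reproduces a tissue", {
  smp <- make_tissue(9, 96L)
  L <- smp$truth
  B <- labels_to_boundary(L)
  D <- memseg:::.dist_to_set(B)
  seeds <- matrix(0L, nrow(L), ncol(L))
  for (lab in seq_len(max(L))) {
    px <- which(L == lab)
    seeds[px[which.max(D[px])]] <- lab
  }
  Lr <- seeded_watershed(-D, seeds)
  expect_identical(unname(Lr > 0), unname(L > 0))
  expect_true(all(Lr[L > 0] == L[L > 0]))
})
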