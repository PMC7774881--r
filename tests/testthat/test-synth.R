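test_that("generation is deterministic and the truth is always valid", {
  s1 <- make_tissue(10, 96L)
  s2 <- make_tissue(10, 96L)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  for (sd in c(1, 5, 9)) {
    smp <- make_tissue(sd, 96L)
    expect_true(isTRUE(validate_labels(smp$truth)))
    expect_equal(dim(smp$image), dim(smp$truth))
    expect_true(all(smp$image >= 0 & smp$image <= 1))
    expect_gte(max(smp$truth), 1)
  }
  # dotted staining also yields a valid pair
  sd <- generate_tissue(tissue_params(field = c(96L, 96L), staining = "dotted",
                                      rng_seed = 3))
  expect_true(isTRUE(validate_labels(sd$truth)))
})

test_that("realized cell counts follow the Poisson expectation", {
  # 1 cell per 10^4 px on a 200x200 field -> lambda = 4
  counts <- c()
  for (sd in 1:200) {
    smp <- tryCatch(
      generate_tissue(tissue_params(field = c(200L, 200L), density = 1,
                                    psf_sigma = 0, noise_sd = 0,
                                    gradient_amplitude = 0, lloyd_iters = 0L,
                                    rng_seed = sd)),
      error = function(e) NULL)  # zero-cell draws error by contract
    counts <- c(counts, if (is.null(smp)) NA else max(smp$truth))
  }
  lam <- 4
  m <- mean(counts, na.rm = TRUE)
  # mean of the zero-truncated Poisson, within 3 standard errors
  expected <- lam / (1 - exp(-lam))
  se <- sqrt(lam) / sqrt(sum(!is.na(counts)))
  expect_lt(abs(m - expected), 3 * se + 0.1)
})

test_that("noiseless continuous membranes are exactly watershed-recoverable", {
  for (sd in 1:3) {
    smp <- generate_tissue(tissue_params(field = c(96L, 96L), psf_sigma = 0,
                                         noise_sd = 0, gradient_amplitude = 0,
                                         rng_seed = sd))
    rep <- average_precision(smp$truth,
                             boundary_to_labels(watershed_lines(smp$image)))
    expect_equal(rep$ap, 1)
    expect_equal(rep$seg, 1)
  }
})

test_that("the giant/tiny mixture produces a bimodal area distribution", {
  smp <- generate_tissue(tissue_params(
    field = c(192L, 192L), density = 40,
    size_mixture = list(giant_fraction = 0.12, area_ratio = 12),
    rng_seed = 7))
  areas <- tabulate(smp$truth[smp$truth > 0])
  areas <- areas[areas > 0]
  km <- stats::kmeans(log(areas), centers = 2, nstart = 5)
  big <- max(km$centers); small <- min(km$centers)
  # two clearly separated log-area clusters with a large mean ratio
  expect_gt(exp(big - small), 4)
  expect_gt(min(table(km$cluster)), 2)
})

test_that("datasets are reproducible from their manifest", {
  d <- withr::local_tempdir()
  params <- list(tissue_params(field = c(64L, 64L), rng_seed = NULL),
                 tissue_params(field = c(64L, 64L), staining = "dotted",
                               rng_seed = NULL))
  ds <- generate_dataset(params, n_per = 3L, seed = 2L, dir = d)
  expect_equal(nrow(ds$manifest), 6L)
  expect_length(ds$samples, 6L)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  # regenerate sample 4 from its manifest row: bit-identical truth
  row <- ds$manifest[4, ]
  p <- params[[row$param_set]]
  p$rng_seed <- row$seed
  again <- generate_tissue(p)
  expect_identical(again$truth, ds$samples[[4]]$truth)
  expect_identical(again$image, ds$samples[[4]]$image)
  # and the files round-trip
  expect_identical(read_labels(row$labels), ds$samples[[4]]$truth)
})

test_that("added noise degrades the plain-watershed baseline monotonically", {
  ap_at <- function(sd_noise) {
    aps <- vapply(1:3, function(sd) {
      smp <- generate_tissue(tissue_params(field = c(96L, 96L), psf_sigma = 1,
                                           noise_sd = sd_noise,
                                           gradient_amplitude = 0,
                                           rng_seed = sd))
      average_precision(smp$truth,
                        boundary_to_labels(watershed_lines(smp$image, h = 0.05)))$ap
    }, numeric(1))
    mean(aps)
  }
  expect_gt(ap_at(0.01), ap_at(0.3))
})
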