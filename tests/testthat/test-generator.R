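test_that("configuration is validated", {
  expect_error(generator_config(image_size = 16), "image_size")
  expect_error(generator_config(treatment_levels = c(0.5, 1.2)), "severities")
  expect_error(generator_config(treatment_levels = c(0.1, 0.9, 0.5)),
               "ordered")
  expect_error(generator_config(slices_per_sample = 0), "slices_per_sample")
  expect_error(generator_config(
    ll_coupling = list(base = 2, slope = 20, noise_sd = -1)), "noise_sd")
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1[[1]]$damaged_slices[[1]]$pixels,
                   d2[[1]]$damaged_slices[[1]]$pixels)
  expect_identical(vapply(d1, `[[`, numeric(1), "liquid_loss_pct"),
                   vapply(d2, `[[`, numeric(1), "liquid_loss_pct"))
  d3 <- generate_dataset(tiny_config(noise_sd = 0.02))
  expect_false(identical(d1[[1]]$fresh_slices[[1]]$pixels,
                         d3[[1]]$fresh_slices[[1]]$pixels))
})

test_that("zero severity produces no damage and identical paired slices", {
  ds <- generate_dataset(tiny_config(treatment_levels = 0, noise_sd = 0))
  for (s in ds) {
    expect_true(all(vapply(s$truth_masks, sum, numeric(1)) == 0))
    expect_equal(s$damage_fraction, 0)
    for (i in seq_along(s$fresh_slices))
      expect_identical(s$fresh_slices[[i]]$pixels,
                       s$damaged_slices[[i]]$pixels)
  }
})

test_that("masks live inside the foreground and slices are paired", {
  ds <- generate_dataset(tiny_config())
  for (s in ds) {
    for (i in seq_along(s$truth_masks)) {
      expect_true(all(!s$truth_masks[[i]] | s$foreground[[i]]))
      expect_identical(dim(s$fresh_slices[[i]]$pixels),
                       dim(s$damaged_slices[[i]]$pixels))
      expect_identical(s$fresh_slices[[i]]$y, 0L)
      expect_identical(s$damaged_slices[[i]]$y, 1L)
    }
    # fresh and damaged agree exactly outside the mask (up to noise): with
    # zero noise they differ only inside the truth mask
  }
  ds0 <- generate_dataset(tiny_config(noise_sd = 0))
  s <- ds0[[1]]
  diffpx <- s$damaged_slices[[1]]$pixels != s$fresh_slices[[1]]$pixels
  expect_true(all(!diffpx | s$truth_masks[[1]]))
})

test_that("severity ordering drives mean damage fraction", {
  wins <- 0L
  n_seeds <- 10L
  for (sd_ in seq_len(n_seeds)) {
    cfg <- generator_config(image_size = 32, n_samples_per_group = 10,
                            slices_per_sample = 2,
                            treatment_levels = c(0.9, 0.5, 0.1), seed = sd_)
    ds <- generate_dataset(cfg)
    g <- vapply(split(vapply(ds, `[[`, numeric(1), "damage_fraction"),
                      vapply(ds, `[[`, integer(1), "group")), mean, numeric(1))
    if (g[1] > g[2] && g[2] > g[3]) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})

test_that("damage-field smoothness bounds the boundary gradient", {
  grad_mag <- function(f) {
    gx <- f[-1, ] - f[-nrow(f), ]
    gy <- f[, -1] - f[, -ncol(f)]
    max(abs(gx), abs(gy))
  }
  set.seed(3)
  rough <- replicate(5, grad_mag(camrel:::grf(64, 2)))
  smooth <- replicate(5, grad_mag(camrel:::grf(64, 9)))
  expect_lt(max(smooth), min(rough))
  expect_lt(max(smooth), 0.5)  # standardized field: gradients shrink ~ 1/sigma
})

test_that("liquid loss follows the affine coupling", {
  expect_equal(simulate_liquid_loss(0, list(base = 2, slope = 20, noise_sd = 0)), 2)
  expect_equal(simulate_liquid_loss(1, list(base = 2, slope = 20, noise_sd = 0)), 22)
  # exact affine function of damage fraction at zero noise
  df <- seq(0, 1, by = 0.05)
  ll <- simulate_liquid_loss(df, list(base = 3, slope = 15, noise_sd = 0))
  expect_equal(ll, 3 + 15 * df)
  expect_error(simulate_liquid_loss(1.5, list(base = 2, slope = 20, noise_sd = 0)),
               "damage_fraction")
  set.seed(1)
  df <- runif(200)
  ll <- simulate_liquid_loss(df, list(base = 2, slope = 20, noise_sd = 1.5))
  expect_gt(cor(df, ll, method = "spearman"), 0)
  expect_true(all(ll >= 0 & ll <= 100))
})

test_that("liquid loss from masses follows the mass-ratio formula", {
  expect_equal(liquid_loss_percent(150, 150), 0)
  expect_equal(liquid_loss_percent(150, 135), 10)
  expect_equal(liquid_loss_percent(100, 0), 100)
  expect_error(liquid_loss_percent(0, 0), "m0")
  expect_error(liquid_loss_percent(100, 101), "mL")
})

test_that("dataset export writes images and metadata", {
  ds <- generate_dataset(tiny_config(n_samples_per_group = 2))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "S01_01_fresh.png")))
  expect_true(file.exists(file.path(dir, "S02_02_mask.png")))
  meta <- read.csv(file.path(dir, "samples.csv"))
  expect_equal(nrow(meta), length(ds))
  expect_true(file.exists(file.path(dir, "config.json")))
})
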