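test_that("IoU matches hand-computed and oracle values", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, !a), 0)
  # both-empty convention
  e <- matrix(FALSE, 2, 2)
  expect_equal(iou(e, e), 1)
  expect_true(is.na(iou(e, e, both_empty = NA)))
  expect_error(iou(a, matrix(FALSE, 3, 3)), "shapes")
  # symmetry, bounds, and pixel-set oracle on random masks
  set.seed(21)
  for (i in 1:100) {
    m1 <- matrix(runif(64) < runif(1), 8, 8)
    m2 <- matrix(runif(64) < runif(1), 8, 8)
    v <- iou(m1, m2)
    expect_identical(v, iou(m2, m1))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_identical(v, iou_oracle(m1, m2))
  }
})

test_that("mean IoU averages per-slice IoUs", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_iou(list(a, a), list(a, a)), 1)
  expect_equal(mean_iou(list(a, a), list(a, !a)), 0.5)
  expect_error(mean_iou(list(a), list(a, a)), "paired")
  set.seed(22)
  as <- replicate(20, matrix(runif(64) < 0.4, 8, 8), simplify = FALSE)
  bs <- replicate(20, matrix(runif(64) < 0.4, 8, 8), simplify = FALSE)
  expect_equal(mean_iou(as, bs),
               mean(mapply(iou_oracle, as, bs)))
  # self-comparison is exactly 1
  expect_equal(mean_iou(as, as), 1)
})

test_that("cross-method agreement is the mean of all unordered pairs", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  ms <- list(m1 = a, m2 = a, m3 = a)
  expect_equal(agreement_across_cams(ms, model = "m")$value, 1)
  # three masks with pairwise IoUs {1, 0, 0}
  disj <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  r <- agreement_across_cams(list(a, a, disj), model = "m", t_cam = 0.5,
                             slice = "s1")
  expect_equal(r$value, 1 / 3)
  expect_equal(r$n_pairs, 3L)
  expect_identical(r$axis_type, "model")
  # six methods -> 15 pairs
  set.seed(23)
  six <- replicate(6, matrix(runif(64) < 0.5, 8, 8), simplify = FALSE)
  r6 <- agreement_across_cams(six, model = "m")
  expect_equal(r6$n_pairs, choose(6, 2))
  pairs <- combn(6, 2)
  expect_equal(r6$value,
               mean(apply(pairs, 2, function(p)
                 iou_oracle(six[[p[1]]], six[[p[2]]]))))
  expect_error(agreement_across_cams(list(a)), "at least 2")
})

test_that("cross-model agreement mirrors the cross-method statistic", {
  set.seed(24)
  six <- replicate(6, matrix(runif(64) < 0.5, 8, 8), simplify = FALSE)
  r <- agreement_across_models(six, method = "gradcam")
  expect_equal(r$n_pairs, 15L)
  expect_identical(r$axis_type, "method")
  # invariance under reordering of the models
  r2 <- agreement_across_models(rev(six), method = "gradcam")
  expect_equal(r$value, r2$value)
  expect_equal(agreement_across_models(list(six[[1]], six[[1]]))$value, 1)
})

test_that("damage fraction counts mask pixels inside the foreground", {
  fg <- matrix(TRUE, 4, 4)
  expect_equal(damage_fraction(fg, fg), 1)
  expect_equal(damage_fraction(matrix(FALSE, 4, 4), fg), 0)
  cb <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)
  expect_equal(damage_fraction(cb, fg), 0.5)
  expect_error(damage_fraction(fg, matrix(FALSE, 4, 4)), "empty foreground")
  # pixels outside the foreground never count
  m <- matrix(TRUE, 4, 4)
  half <- matrix(rep(c(TRUE, FALSE), each = 8), 4, 4)
  expect_equal(damage_fraction(m, half), 1)
})

test_that("liquid-loss correlation reports Spearman's rho", {
  r <- correlate_with_liquid_loss(1:10 / 10, 2 + (1:10)^2)
  expect_equal(r$rho, 1)
  r2 <- correlate_with_liquid_loss(1:10 / 10, 20 - (1:10))
  expect_equal(r2$rho, -1)
  expect_identical(r$method, "spearman")
  expect_equal(r$n, 10L)
  expect_warning(correlate_with_liquid_loss(rep(0.5, 5), 1:5), "constant")
  expect_error(correlate_with_liquid_loss(c(0.1, 0.2), c(1, 2)), "at least 3")
})

test_that("generator coupling yields detectable positive correlations", {
  hits <- 0L
  for (sd_ in 1:10) {
    cfg <- generator_config(image_size = 32, n_samples_per_group = 10,
                            slices_per_sample = 2,
                            treatment_levels = c(0.9, 0.5, 0.1), seed = sd_)
    ds <- generate_dataset(cfg)
    df <- vapply(ds, `[[`, numeric(1), "damage_fraction")
    ll <- vapply(ds, `[[`, numeric(1), "liquid_loss_pct")
    r <- correlate_with_liquid_loss(df, ll)
    if (r$rho > 0 && r$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("group comparison behaves under null and separated alternatives", {
  g0 <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  r0 <- compare_groups(g0)
  expect_lt(r0$H, 1e-8)
  expect_gt(r0$p_value, 0.99)
  r1 <- compare_groups(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_lt(r1$p_value, 0.05)
  # label symmetry: permuting group membership jointly with values
  set.seed(25)
  v <- rnorm(12); lab <- rep(1:3, each = 4)
  perm <- sample(12)
  h1 <- compare_groups(split(v, lab))$H
  h2 <- compare_groups(split(v[perm], lab[perm]))$H
  expect_equal(h1, h2)
  expect_error(compare_groups(list(a = 1:3)), "at least 2")
  expect_error(compare_groups(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("random masks match the requested area inside the foreground", {
  set.seed(26)
  fg <- matrix(runif(256) < 0.7, 16, 16)
  rm <- random_mask(40, fg)
  expect_equal(sum(rm), 40)
  expect_true(all(!rm | fg))
  expect_equal(sum(random_mask(10000, fg)), sum(fg))
})
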