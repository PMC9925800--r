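make_proj_net <- function(K = 3, size = 8, seed = 1, positive_head = FALSE) {
  set.seed(seed)
  w <- array(rnorm(9 * K, sd = 0.5), c(3, 3, 1, K))
  fc <- matrix(rnorm(2 * K, sd = 1), K, 2)
  if (positive_head) fc[, 2] <- abs(fc[, 2])
  list(net = toy_gap_net(w, fc_w = fc, input_size = size), fc = fc)
}

test_that("Grad-CAM equals the CAM weight projection on GAP + linear nets", {
  p <- make_proj_net(K = 4, seed = 2)
  img <- matrix(runif(64), 8, 8)
  a <- activations(p$net, img, "conv1")
  proj <- matrix(matrix(a, ncol = 4) %*% p$fc[, 2], 8, 8)  # classic CAM
  oracle <- camrel:::normalize_heatmap(pmax(proj, 0))
  h <- grad_cam(p$net, img, "conv1", class_index = 1L)
  expect_lt(max(abs(unclass(h) - oracle)), 1e-6)
})

test_that("zero gradients give an all-zero Grad-CAM heatmap", {
  p <- make_proj_net(K = 3, seed = 3)
  p$fc[, 2] <- 0
  net <- toy_gap_net(array(rnorm(27, sd = 0.5), c(3, 3, 1, 3)), fc_w = p$fc)
  set.seed(1)
  h <- grad_cam(net, matrix(runif(64), 8, 8), "conv1", 1L)
  expect_true(all(h == 0))
  hpp <- grad_cam_pp(net, matrix(runif(64), 8, 8), "conv1", 1L)
  expect_true(all(hpp == 0))
})

test_that("single-channel Grad-CAM is the rectified normalized activation map", {
  w <- array(rnorm(9, sd = 0.5), c(3, 3, 1, 1))
  set.seed(5)
  net <- toy_gap_net(w, fc_w = matrix(c(0, 2), 1, 2), act = "none")
  img <- matrix(runif(64), 8, 8)
  a <- activations(net, img, "conv1")[, , 1]
  h <- grad_cam(net, img, "conv1", 1L)
  expect_equal(unclass(h), camrel:::normalize_heatmap(pmax(a, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Grad-CAM++ reduces to Grad-CAM for spatially constant positive gradients", {
  p <- make_proj_net(K = 4, seed = 7, positive_head = TRUE)
  img <- matrix(runif(64), 8, 8)
  h1 <- grad_cam(p$net, img, "conv1", 1L)
  h2 <- grad_cam_pp(p$net, img, "conv1", 1L)
  expect_lt(max(abs(unclass(h1) - unclass(h2))), 1e-6)
})

test_that("Grad-CAM++ alpha closed form matches a higher-order numerical oracle", {
  p <- make_proj_net(K = 2, seed = 9)
  net <- p$net
  net$layers[[1]]$act <- "none"    # linear in A everywhere
  img <- matrix(runif(64, 0.2, 0.8), 8, 8)
  a <- activations(net, img, "conv1")
  g <- class_gradient(net, img, "conv1", 1L)
  alpha <- camrel:::gradcampp_alpha_raw(a, g)
  f <- function(v) exp(camrel:::forward_from(net, "conv1", v)[1, 2])
  h <- 5e-2   # the exp-score path is linear in A, so a large step is safe
  s_k <- colSums(matrix(a, ncol = 2))
  set.seed(1)
  for (q in sample(length(a), 12)) {
    k <- (q - 1) %/% 64 + 1
    fd <- vapply(c(2, 1, 0, -1, -2), function(m) {
      v <- a; v[q] <- v[q] + m * h; f(v)
    }, numeric(1))
    d2 <- (fd[2] - 2 * fd[3] + fd[4]) / h^2
    d3 <- (fd[1] - 2 * fd[2] + 2 * fd[4] - fd[5]) / (2 * h^3)
    alpha_num <- d2 / (2 * d2 + s_k[k] * d3)
    expect_lt(abs(alpha[q] - alpha_num), 1e-5)
  }
})

test_that("Score-CAM weights are a probability vector and obey closed forms", {
  net <- fd_test_net("plain", input_size = 8, seed = 5)
  img <- matrix(runif(64), 8, 8)
  h <- score_cam(net, img, "mid", 1L)
  w <- attr(h, "weights")
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # single channel: softmax over a singleton is 1 and the map is the
  # rectified normalized activation map
  w1 <- array(rnorm(9, sd = 0.5), c(3, 3, 1, 1))
  net1 <- toy_gap_net(w1, fc_w = matrix(c(0, 1), 1, 2), act = "none")
  h1 <- score_cam(net1, img, "conv1", 1L)
  expect_equal(attr(h1, "weights"), 1)
  a1 <- activations(net1, img, "conv1")[, , 1]
  expect_equal(unclass(h1), camrel:::normalize_heatmap(pmax(a1, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("duplicated channels share the weight and reproduce the map", {
  w1 <- array(rnorm(9, sd = 0.5), c(3, 3, 1, 1))
  w2 <- array(c(w1, w1), c(3, 3, 1, 2))
  fc2 <- matrix(c(0, 0, 0.5, 0.5), 2, 2)
  net1 <- toy_gap_net(w1, fc_w = matrix(c(0, 1), 1, 2))
  net2 <- toy_gap_net(w2, fc_w = fc2)
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  h2 <- score_cam(net2, img, "conv1", 1L)
  expect_equal(attr(h2, "weights"), c(0.5, 0.5), tolerance = 1e-12)
  h1 <- score_cam(net1, img, "conv1", 1L)
  expect_equal(unclass(h1), unclass(h2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("channel masks are invariant to positive rescaling of a channel", {
  net <- fd_test_net("plain", input_size = 8, seed = 5)
  img <- matrix(runif(64), 8, 8)
  a <- activations(net, img, "mid")
  a10 <- a
  a10[, , 1] <- 10 * a10[, , 1]
  w <- camrel:::scorecam_channel_weights(net, img, a, 1L)
  w10 <- camrel:::scorecam_channel_weights(net, img, a10, 1L)
  expect_equal(w, w10, tolerance = 1e-12)
})

test_that("Faster Score-CAM restricts to high-variance channels", {
  # K <= top_n: identical to Score-CAM
  p <- make_proj_net(K = 4, seed = 11)
  img <- matrix(runif(64), 8, 8)
  hs <- score_cam(p$net, img, "conv1", 1L)
  hf <- faster_score_cam(p$net, img, "conv1", 1L, top_n = 10)
  expect_equal(unclass(hs), unclass(hf), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero channels are excluded and the result equals Score-CAM on the
  # non-zero channels only
  set.seed(12)
  wnz <- array(rnorm(9 * 2, sd = 0.5), c(3, 3, 1, 2))
  w4 <- array(0, c(3, 3, 1, 4))
  w4[, , , 1:2] <- wnz
  fc4 <- matrix(rnorm(8), 4, 2)
  fc2 <- fc4[1:2, , drop = FALSE]
  net4 <- toy_gap_net(w4, fc_w = fc4)
  net2 <- toy_gap_net(wnz, fc_w = fc2)
  hf4 <- faster_score_cam(net4, img, "conv1", 1L, top_n = 2)
  expect_setequal(attr(hf4, "channels"), 1:2)  # ranked by variance, descending
  hs2 <- score_cam(net2, img, "conv1", 1L)
  expect_equal(unclass(hf4), unclass(hs2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # variance ties break deterministically toward the lower channel index
  wdup <- array(c(wnz[, , , 1], wnz[, , , 1]), c(3, 3, 1, 2))
  netdup <- toy_gap_net(wdup, fc_w = matrix(rnorm(4), 2, 2))
  hd <- faster_score_cam(netdup, img, "conv1", 1L, top_n = 1)
  expect_identical(attr(hd, "channels"), 1L)
})

test_that("Layer-CAM implements the gradient-deviation weighting and tanh rescale", {
  # spatially constant gradients: deviation from the mean is 0 -> zero map
  p <- make_proj_net(K = 3, seed = 13, positive_head = TRUE)
  img <- matrix(runif(64), 8, 8)
  h0 <- layer_cam(p$net, img, layers = "conv1", mode = "deviation")
  expect_true(all(h0 == 0))
  # classic mode uses the raw gradient and is non-zero here
  hc <- layer_cam(p$net, img, layers = "conv1", mode = "classic")
  expect_gt(max(hc), 0)
  # the pre-normalization maximum is tanh(gamma) whenever max(M) > 0;
  # conv1 sits above a pooling stage, so its gradients vary spatially
  net <- fd_test_net("plain", input_size = 8, seed = 5)
  h <- layer_cam(net, img, layers = "conv1", mode = "deviation")
  expect_gt(max(h), 0)
  expect_equal(attr(h, "prenorm_max"), tanh(2), tolerance = 1e-12)
  hg <- layer_cam(net, img, layers = "conv1", gamma = 3)
  expect_equal(attr(hg, "prenorm_max"), tanh(3), tolerance = 1e-12)
  # fusing a layer with itself changes nothing
  h2 <- layer_cam(net, img, layers = c("conv1", "conv1"), mode = "deviation")
  expect_equal(unclass(h), unclass(h2), ignore_attr = TRUE)
  # multi-layer default set runs shallow-to-deep
  hm <- layer_cam(net, img)
  expect_equal(dim(hm), c(8L, 8L))
})

test_that("every method yields normalized deterministic heatmaps", {
  net <- fd_test_net("residual", input_size = 8, seed = 6)
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  for (me in cam_methods()) {
    h1 <- compute_cam(me, net, img)
    h2 <- compute_cam(me, net, img)
    expect_identical(unclass(h1), unclass(h2))
    expect_gte(min(h1), 0)
    expect_lte(max(h1), 1)
    expect_true(max(h1) == 1 || all(h1 == 0))
    expect_equal(dim(h1), c(8L, 8L))
  }
})

test_that("binarization thresholds with >= and nests across thresholds", {
  m <- matrix(c(0.2, 0.5, 0.6, 0.9), 2, 2)
  expect_identical(binarize(m, 0.5), matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_true(all(binarize(matrix(1, 3, 3), 0.5)))
  expect_error(binarize(m, 0), "t_cam")
  expect_error(binarize(m, 1), "t_cam")
  # strict mode and foreground restriction
  expect_identical(binarize(m, 0.5, strict = TRUE),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  fg <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_identical(binarize(m, 0.5, foreground = fg),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  set.seed(8)
  hm <- camrel:::normalize_heatmap(matrix(runif(256), 16, 16))
  grid <- seq(0.1, 0.9, by = 0.1)
  for (i in seq_len(length(grid) - 1)) {
    lo <- binarize(hm, grid[i])
    hi <- binarize(hm, grid[i + 1])
    expect_true(all(!hi | lo))  # mask(t') subset of mask(t)
  }
})
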