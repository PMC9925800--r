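# Hand-constructed networks and oracles shared across tests.

# Naive direct convolution (same padding, stride 1, cross-correlation),
# independent of the compiled path.
naive_conv <- function(x, warr, b) {
  k <- dim(warr)[1]; pad <- (k - 1) / 2
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(warr)[4]
  out <- array(0, c(H, W, Cout))
  for (co in 1:Cout) for (i in 1:H) for (j in 1:W) {
    s <- b[co]
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      ii <- i + ki - 1 - pad; jj <- j + kj - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj, ci] * warr[ki, kj, ci, co]
    }
    out[i, j, co] <- s
  }
  out
}

# A one-conv-layer GAP + linear-head network with hand-set weights.
# conv_w: array (k, k, 1, K); fc_w: matrix K x 2. No input transform.
toy_gap_net <- function(conv_w, conv_b = NULL, fc_w, fc_b = NULL,
                        input_size = 8L, act = "relu") {
  K <- dim(conv_w)[4]
  conv <- camrel:::new_conv("conv1", 1L, K, k = dim(conv_w)[1], act = act)
  conv$W <- camrel:::conv_weight_matrix(conv_w)
  if (!is.null(conv_b)) conv$b <- conv_b
  fc <- camrel:::new_dense("fc", K, 2L)
  fc$W <- fc_w
  if (!is.null(fc_b)) fc$b <- fc_b
  structure(list(architecture = "toy",
                 layers = list(conv, list(name = "gap", type = "gap"), fc),
                 input_size = as.integer(input_size), n_classes = 2L,
                 center = 0, scale = 1, trained = TRUE, trace = NULL),
            class = "cam_cnn")
}

# Small differentiable-by-construction networks (< 1e3 parameters) for
# finite-difference checks: weights are kept small and biases positive so
# ReLU units stay active and max-pool windows are tie-free almost surely.
fd_test_net <- function(kind = c("plain", "residual", "inception"),
                        input_size = 8L, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  soften <- function(l) {
    if (l$type %in% c("conv", "dense")) {
      l$W[] <- rnorm(length(l$W), sd = 0.08)
      l$b[] <- 0.3
    } else if (l$type == "res") {
      l$conv1 <- soften(l$conv1); l$conv2 <- soften(l$conv2)
    } else if (l$type == "incep") {
      l$b1 <- soften(l$b1); l$b2 <- soften(l$b2)
    }
    l
  }
  mid <- switch(kind,
    plain = camrel:::new_conv("mid", 3L, 4L),
    residual = camrel:::new_res("mid", 3L),
    inception = camrel:::new_incep("mid", 3L, 2L, 2L))
  out_ch <- switch(kind, plain = 4L, residual = 3L, inception = 4L)
  layers <- list(camrel:::new_conv("conv1", 1L, 3L),
                 list(name = "pool1", type = "pool"),
                 mid,
                 list(name = "gap", type = "gap"),
                 camrel:::new_dense("fc", out_ch, 2L))
  layers <- lapply(layers, soften)
  structure(list(architecture = paste0("fd_", kind), layers = layers,
                 input_size = as.integer(input_size), n_classes = 2L,
                 center = 0, scale = 1, trained = TRUE, trace = NULL),
            class = "cam_cnn")
}

n_params <- function(model) {
  cnt <- function(l) switch(l$type,
    conv = , dense = length(l$W) + length(l$b),
    res = cnt(l$conv1) + cnt(l$conv2),
    incep = cnt(l$b1) + cnt(l$b2),
    0L)
  sum(vapply(model$layers, cnt, numeric(1)))
}

# Pixel-set IoU oracle: set operations on cell indices, independent of the
# vectorised mask arithmetic in iou().
iou_oracle <- function(a, b) {
  ca <- which(a != 0); cb <- which(b != 0)
  u <- union(ca, cb)
  if (length(u) == 0) return(1)
  length(intersect(ca, cb)) / length(u)
}

# Small ready-made dataset for preprocessing/pipeline tests.
tiny_config <- function(image_size = 32, n_samples_per_group = 4,
                        slices_per_sample = 2, treatment_levels = 0.9,
                        seed = 42, ...) {
  generator_config(image_size = image_size,
                   n_samples_per_group = n_samples_per_group,
                   slices_per_sample = slices_per_sample,
                   treatment_levels = treatment_levels, seed = seed, ...)
}
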