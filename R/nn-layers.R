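# Layer primitives for the small-CNN engine. All spatial tensors are
# column-major arrays H x W x C x N; flat (post-GAP) tensors are N x C
# matrices. Convolutions are "same"-padded, stride-1 cross-correlations with
# kernels computed in compiled code (src/conv.cpp). Each forward returns
# list(out, cache); each backward takes (dout, cache) and returns
# list(dx, grads).

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

# Weight matrix convention: a conv kernel array of dim (k, k, cin, cout),
# element [ki, kj, ci, co] applied to input pixel (i + ki - 1 - pad,
# j + kj - 1 - pad, ci), stored column-major as a (k*k*cin) x cout matrix.
conv_weight_matrix <- function(w) {
  d <- dim(w)
  stopifnot(length(d) == 4L, d[1] == d[2])
  matrix(w, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

new_conv <- function(name, cin, cout, k = 3L, act = c("relu", "none")) {
  act <- match.arg(act)
  list(name = name, type = "conv", k = as.integer(k), cin = cin, cout = cout,
       act = act, W = matrix(0, k * k * cin, cout), b = numeric(cout))
}

conv_fwd_layer <- function(layer, x) {
  z <- conv_fwd_cpp(x, dim(x), layer$W, layer$b, layer$k)
  out <- if (layer$act == "relu") pmax(z, 0) else z
  list(out = out, cache = list(x = x, z = z))
}

conv_bwd_layer <- function(layer, dout, cache, need_dx = TRUE) {
  dz <- if (layer$act == "relu") dout * (cache$z > 0) else dout
  bw <- conv_bwd_cpp(cache$x, dim(cache$x), dz, layer$W, layer$k, need_dx)
  list(dx = if (need_dx) bw$dx else NULL,
       grads = list(W = bw$dW, b = as.numeric(bw$db)))
}

# 2x2 max pooling, stride 2; ties broken deterministically in favour of the
# first position in scan order (top-left, bottom-left, top-right,
# bottom-right).
pool_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  a1 <- x[io, jo, , , drop = FALSE]
  a2 <- x[ie, jo, , , drop = FALSE]
  a3 <- x[io, je, , , drop = FALSE]
  a4 <- x[ie, je, , , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  s1 <- a1 == m
  s2 <- (a2 == m) & !s1
  s3 <- (a3 == m) & !(s1 | s2)
  s4 <- !(s1 | s2 | s3)
  list(out = m, cache = list(sel = list(s1, s2, s3, s4), dims = d))
}

pool_bwd <- function(dout, cache) {
  d <- cache$dims
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  dx <- array(0, d)
  sel <- cache$sel
  dx[io, jo, , ] <- dout * sel[[1]]
  dx[ie, jo, , ] <- dout * sel[[2]]
  dx[io, je, , ] <- dout * sel[[3]]
  dx[ie, je, , ] <- dout * sel[[4]]
  list(dx = dx, grads = NULL)
}

gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cm <- colMeans(array(x, c(hw, d[3] * d[4])))        # length C*N
  out <- t(matrix(cm, d[3], d[4]))                    # N x C
  list(out = out, cache = list(dims = d))
}

gap_bwd <- function(dout, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  g <- t(dout) / hw                                   # C x N
  dx <- array(rep(as.vector(g), each = hw), d)
  list(dx = dx, grads = NULL)
}

new_dense <- function(name, cin, cout) {
  list(name = name, type = "dense", cin = cin, cout = cout,
       W = matrix(0, cin, cout), b = numeric(cout))
}

dense_fwd <- function(layer, x) {
  out <- x %*% layer$W + rep(layer$b, each = nrow(x))
  list(out = out, cache = list(x = x))
}

dense_bwd <- function(layer, dout, cache) {
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# Residual block: relu(conv2(relu(conv1(x))) + x), channel-preserving.
new_res <- function(name, channels) {
  list(name = name, type = "res",
       conv1 = new_conv(paste0(name, "_a"), channels, channels, act = "relu"),
       conv2 = new_conv(paste0(name, "_b"), channels, channels, act = "none"))
}

res_fwd <- function(layer, x) {
  f1 <- conv_fwd_layer(layer$conv1, x)
  f2 <- conv_fwd_layer(layer$conv2, f1$out)
  s <- f2$out + x
  list(out = pmax(s, 0), cache = list(c1 = f1$cache, c2 = f2$cache, s = s))
}

res_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  ds <- dout * (cache$s > 0)
  b2 <- conv_bwd_layer(layer$conv2, ds, cache$c2, TRUE)
  b1 <- conv_bwd_layer(layer$conv1, b2$dx, cache$c1, need_dx)
  dx <- if (need_dx) b1$dx + ds else NULL
  list(dx = dx, grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

# Parallel multi-scale block: channel concatenation of a 1x1 and a 3x3
# convolution branch, both ReLU-activated.
new_incep <- function(name, cin, c1, c2) {
  list(name = name, type = "incep", c1 = c1, c2 = c2,
       b1 = new_conv(paste0(name, "_1x1"), cin, c1, k = 1L, act = "relu"),
       b2 = new_conv(paste0(name, "_3x3"), cin, c2, k = 3L, act = "relu"))
}

incep_fwd <- function(layer, x) {
  f1 <- conv_fwd_layer(layer$b1, x)
  f2 <- conv_fwd_layer(layer$b2, x)
  d <- dim(f1$out)
  out <- array(0, c(d[1], d[2], layer$c1 + layer$c2, d[4]))
  out[, , seq_len(layer$c1), ] <- f1$out
  out[, , layer$c1 + seq_len(layer$c2), ] <- f2$out
  list(out = out, cache = list(b1 = f1$cache, b2 = f2$cache))
}

incep_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  d1 <- dout[, , seq_len(layer$c1), , drop = FALSE]
  d2 <- dout[, , layer$c1 + seq_len(layer$c2), , drop = FALSE]
  b1 <- conv_bwd_layer(layer$b1, d1, cache$b1, need_dx)
  b2 <- conv_bwd_layer(layer$b2, d2, cache$b2, need_dx)
  dx <- if (need_dx) b1$dx + b2$dx else NULL
  list(dx = dx, grads = list(b1 = b1$grads, b2 = b2$grads))
}

layer_fwd <- function(layer, x) {
  switch(layer$type,
         conv = conv_fwd_layer(layer, x),
         pool = pool_fwd(x),
         gap = gap_fwd(x),
         dense = dense_fwd(layer, x),
         res = res_fwd(layer, x),
         incep = incep_fwd(layer, x),
         stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  switch(layer$type,
         conv = conv_bwd_layer(layer, dout, cache, need_dx),
         pool = pool_bwd(dout, cache),
         gap = gap_bwd(dout, cache),
         dense = dense_bwd(layer, dout, cache),
         res = res_bwd(layer, dout, cache, need_dx),
         incep = incep_bwd(layer, dout, cache, need_dx),
         stop("unknown layer type: ", layer$type))
}

# He-normal initialisation for all conv/dense weights in a layer list.
init_layer <- function(layer) {
  he <- function(w, fan_in) {
    w[] <- rnorm(length(w), sd = sqrt(2 / fan_in))
    w
  }
  switch(layer$type,
         conv = { layer$W <- he(layer$W, layer$k^2 * layer$cin); layer },
         dense = { layer$W <- he(layer$W, layer$cin); layer },
         res = { layer$conv1 <- init_layer(layer$conv1)
                 layer$conv2 <- init_layer(layer$conv2); layer },
         incep = { layer$b1 <- init_layer(layer$b1)
                   layer$b2 <- init_layer(layer$b2); layer },
         layer)
}

# Parameter updates: walk the (possibly nested) grads structure.
sgd_update <- function(layer, grads, vel, lr, momentum) {
  if (is.null(grads)) return(list(layer = layer, vel = vel))
  if (layer$type %in% c("conv", "dense")) {
    if (is.null(vel)) vel <- list(W = 0 * layer$W, b = 0 * layer$b)
    vel$W <- momentum * vel$W - lr * grads$W
    vel$b <- momentum * vel$b - lr * grads$b
    layer$W <- layer$W + vel$W
    layer$b <- layer$b + vel$b
  } else if (layer$type == "res") {
    if (is.null(vel)) vel <- list(conv1 = NULL, conv2 = NULL)
    u1 <- sgd_update(layer$conv1, grads$conv1, vel$conv1, lr, momentum)
    u2 <- sgd_update(layer$conv2, grads$conv2, vel$conv2, lr, momentum)
    layer$conv1 <- u1$layer; layer$conv2 <- u2$layer
    vel <- list(conv1 = u1$vel, conv2 = u2$vel)
  } else if (layer$type == "incep") {
    if (is.null(vel)) vel <- list(b1 = NULL, b2 = NULL)
    u1 <- sgd_update(layer$b1, grads$b1, vel$b1, lr, momentum)
    u2 <- sgd_update(layer$b2, grads$b2, vel$b2, lr, momentum)
    layer$b1 <- u1$layer; layer$b2 <- u2$layer
    vel <- list(b1 = u1$vel, b2 = u2$vel)
  }
  list(layer = layer, vel = vel)
}
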