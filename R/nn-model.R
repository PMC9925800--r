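#' Small convolutional classifier backbones
#'
#' Construct an untrained convolutional network for binary image
#' classification. Three desk-scale architecture families are provided that
#' preserve the structural distinctions of the large ImageNet backbones
#' usually used in this setting: a plain sequential stack (`"plain"`, VGG
#' style), a residual variant (`"residual"`), and a parallel multi-branch
#' variant (`"inception"`). All end in global average pooling and a linear
#' head so that pre-softmax class scores, layer activations, and
#' class-score gradients are available to the CAM methods.
#'
#' @param architecture one of [cam_cnn_architectures()].
#' @param input_size side length of the (square, single-channel) input image;
#'   must be a multiple of 4 and at least 16.
#' @param n_classes number of output classes (2: fresh vs damaged).
#' @param seed optional integer; when given, weight initialisation is seeded.
#' @param center,scale fixed input transform applied at the network entry:
#'   `(x - center) * scale`. The default maps `[0, 1]` images to `[-1, 1]`,
#'   which conditions SGD much better than raw intensities; toy networks in
#'   closed-form tests can disable it with `center = 0, scale = 1`.
#' @return an object of class `cam_cnn`.
#' @examples
#' m <- cam_cnn("plain", input_size = 32, seed = 1)
#' m
#' @export
cam_cnn <- function(architecture = cam_cnn_architectures(), input_size = 64,
                    n_classes = 2L, seed = NULL, center = 0.5, scale = 2) {
  architecture <- match.arg(architecture)
  stopifnot(input_size >= 16, input_size %% 4 == 0)
  layers <- switch(architecture,
    plain = list(
      new_conv("conv1", 1L, 8L),
      list(name = "pool1", type = "pool"),
      new_conv("conv2", 8L, 16L),
      list(name = "pool2", type = "pool"),
      new_conv("conv3", 16L, 32L),
      list(name = "gap", type = "gap"),
      new_dense("fc", 32L, n_classes)),
    residual = list(
      new_conv("conv1", 1L, 8L),
      list(name = "pool1", type = "pool"),
      new_conv("conv2", 8L, 16L),
      list(name = "pool2", type = "pool"),
      new_res("res1", 16L),
      list(name = "gap", type = "gap"),
      new_dense("fc", 16L, n_classes)),
    inception = list(
      new_conv("conv1", 1L, 8L),
      list(name = "pool1", type = "pool"),
      new_conv("conv2", 8L, 16L),
      list(name = "pool2", type = "pool"),
      new_incep("incep1", 16L, 8L, 8L),
      list(name = "gap", type = "gap"),
      new_dense("fc", 16L, n_classes)))
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(layers, init_layer)
  structure(list(architecture = architecture, layers = layers,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 center = center, scale = scale,
                 trained = FALSE, trace = NULL),
            class = "cam_cnn")
}

#' @rdname cam_cnn
#' @export
cam_cnn_architectures <- function() c("plain", "residual", "inception")

#' Spatial layers usable as CAM targets
#'
#' `last_conv_layer()` names the deepest spatial layer of a model (the usual
#' CAM target); `stage_layers()` names the last spatial layer of each
#' resolution stage (the default multi-layer set for Layer-CAM, shallow to
#' deep).
#'
#' @param model a [cam_cnn] model.
#' @return character vector of layer names.
#' @export
last_conv_layer <- function(model) {
  nm <- stage_layers(model)
  nm[length(nm)]
}

#' @rdname last_conv_layer
#' @export
stage_layers <- function(model) {
  spatial <- vapply(model$layers, function(l)
    l$type %in% c("conv", "res", "incep"), logical(1))
  vapply(model$layers[spatial], `[[`, character(1), "name")
}

layer_index <- function(model, layer) {
  nm <- vapply(model$layers, `[[`, character(1), "name")
  i <- match(layer, nm)
  if (is.na(i)) stop("unknown layer: '", layer, "' (layers: ",
                     paste(nm, collapse = ", "), ")")
  i
}

# Full forward pass; optionally keeps per-layer caches for backprop.
nn_forward <- function(model, x, keep = FALSE) {
  x <- (as_batch(x) - model$center) * model$scale
  caches <- if (keep) vector("list", length(model$layers))
  outs <- if (keep) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    f <- layer_fwd(model$layers[[i]], x)
    x <- f$out
    if (keep) { caches[[i]] <- f$cache; outs[[i]] <- f$out }
  }
  list(scores = x, caches = caches, outs = outs)
}

# Continue the forward pass from the output of a named layer.
forward_from <- function(model, layer, a) {
  i <- layer_index(model, layer)
  x <- as_batch(a)
  for (j in seq(i + 1L, length(model$layers))) {
    x <- layer_fwd(model$layers[[j]], x)$out
  }
  x
}

# Backward pass from pre-softmax score gradients down to (and not through)
# layer index `upto`; returns per-layer parameter grads and the gradient
# flowing into the output of layer `upto` (dx).
nn_backward <- function(model, caches, dscores, upto = 0L) {
  n <- length(model$layers)
  grads <- vector("list", n)
  d <- dscores
  for (i in seq(n, upto + 1L)) {
    need_dx <- i > upto + 1L || upto > 0L
    bw <- layer_bwd(model$layers[[i]], d, caches[[i]], need_dx = need_dx)
    grads[i] <- list(bw$grads)   # [[<-]] with NULL would drop the element
    d <- bw$dx
  }
  list(grads = grads, dx = d)
}

#' Layer activations of a trained or untrained model
#'
#' Returns the activation tensor `A` (height x width x channels) produced by
#' a named spatial layer for a single input image. For convolutional layers
#' the activations are post-ReLU feature maps, the tensor the CAM methods
#' operate on.
#'
#' @param model a [cam_cnn] model.
#' @param image numeric matrix (grayscale image in `[0, 1]`).
#' @param layer layer name; defaults to the deepest spatial layer.
#' @return 3-D array H x W x K.
#' @export
activations <- function(model, image, layer = last_conv_layer(model)) {
  i <- layer_index(model, layer)
  x <- (as_batch(image) - model$center) * model$scale
  for (j in seq_len(i)) x <- layer_fwd(model$layers[[j]], x)$out
  if (length(dim(x)) != 4L)
    stop("layer '", layer, "' is not spatial")
  array(x, dim(x)[1:3])
}

#' Gradient of a pre-softmax class score w.r.t. layer activations
#'
#' Computes `dY(c)/dA_k(i,j)` where `Y(c)` is the pre-softmax score of the
#' requested class and `A` the activation tensor of the named layer, by
#' backpropagation through the layers above it.
#'
#' @inheritParams activations
#' @param class_index class label (0 = fresh, 1 = damaged); the score of
#'   column `class_index + 1` is differentiated.
#' @return 3-D array with the same shape as [activations()].
#' @export
class_gradient <- function(model, image, layer = last_conv_layer(model),
                           class_index = 1L) {
  stopifnot(class_index >= 0, class_index < model$n_classes)
  i <- layer_index(model, layer)
  fw <- nn_forward(model, image, keep = TRUE)
  if (length(dim(fw$outs[[i]])) != 4L)
    stop("layer '", layer, "' is not spatial")
  dsc <- matrix(0, nrow(fw$scores), ncol(fw$scores))
  dsc[, class_index + 1L] <- 1
  bw <- nn_backward(model, fw$caches, dsc, upto = i)
  array(bw$dx, dim(fw$outs[[i]])[1:3])
}

#' Class scores of channel-masked inputs
#'
#' Multiplies the input image element-wise by each mask (a `[0, 1]` map at
#' input resolution) and returns the pre-softmax class scores of the masked
#' images, evaluated in one batch. This is the score oracle used by
#' Score-CAM.
#'
#' @inheritParams activations
#' @param masks list of numeric matrices, same size as `image`, values in
#'   `[0, 1]`.
#' @return numeric matrix, one row per mask, one column per class.
#' @export
masked_scores <- function(model, image, masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  d <- dim(image)
  ok <- vapply(masks, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("mask shape does not match image shape")
  x <- array(0, c(d[1], d[2], 1L, length(masks)))
  for (i in seq_along(masks)) x[, , 1L, i] <- image * masks[[i]]
  nn_forward(model, x)$scores
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum, mini-batches, and early
#' stopping on validation accuracy (training stops when the validation
#' accuracy has not improved for `patience` epochs; the best-validation
#' weights are restored).
#'
#' @param learning_rate SGD step size (default 0.02; see the methods
#'   vignette for why the desk-scale epoch budget needs a larger step than
#'   full-scale training protocols use).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs maximum number of epochs (default 60).
#' @param patience epochs without validation improvement before stopping
#'   (default 15); must be smaller than `max_epochs`.
#' @param momentum classical momentum coefficient (default 0.9).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.02, batch_size = 32L,
                         max_epochs = 60L, patience = 15L, momentum = 0.9) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience < max_epochs,
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), momentum = momentum),
            class = "train_config")
}

batch_scores <- function(model, x, chunk = 64L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$n_classes)
  for (s in seq(1L, n, chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- nn_forward(model, x[, , , s:e, drop = FALSE])$scores
  }
  out
}

nn_accuracy <- function(model, x, y, chunk = 64L) {
  sc <- batch_scores(model, x, chunk)
  mean(max.col(sc, ties.method = "first") - 1L == y)
}

#' Train a classifier
#'
#' Trains a [cam_cnn] with mini-batch SGD on the softmax cross-entropy loss.
#' Deterministic given `seed` (single-threaded BLAS assumed).
#'
#' @param model an (untrained or trained) [cam_cnn].
#' @param data list with elements `train` and `val`, each a list with `x`
#'   (array H x W x 1 x N, values in `[0, 1]`) and `y` (integer labels 0/1).
#'   See [dataset_tensors()].
#' @param config a [train_config()].
#' @param seed integer seed for shuffling (and, before first use, weight
#'   initialisation when the model was built without one).
#' @return the trained model; `$trace` holds a per-epoch data frame with
#'   training loss/accuracy and validation accuracy.
#' @export
cnn_train <- function(model, data, config = train_config(), seed = 1L) {
  stopifnot(inherits(model, "cam_cnn"))
  xt <- data$train$x; yt <- as.integer(data$train$y)
  xv <- data$val$x;   yv <- as.integer(data$val$y)
  if (is.null(xt) || dim(xt)[4] == 0) stop("empty training partition")
  if (is.null(xv) || dim(xv)[4] == 0) stop("empty validation partition")
  set.seed(seed)
  n <- dim(xt)[4]
  vel <- vector("list", length(model$layers))
  best <- list(acc = -Inf, layers = model$layers, epoch = 0L)
  trace <- NULL
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_hit <- 0
    for (s in seq(1L, n, config$batch_size)) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- xt[, , , idx, drop = FALSE]
      yb <- yt[idx]
      fw <- nn_forward(model, xb, keep = TRUE)
      p <- softmax_rows(fw$scores)
      m <- length(idx)
      picked <- cbind(seq_len(m), yb + 1L)
      loss <- -mean(log(pmax(p[picked], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ep_loss <- ep_loss + loss * m
      ep_hit <- ep_hit + sum(max.col(p, ties.method = "first") - 1L == yb)
      dsc <- p
      dsc[picked] <- dsc[picked] - 1
      dsc <- dsc / m
      bw <- nn_backward(model, fw$caches, dsc, upto = 0L)
      for (i in seq_along(model$layers)) {
        u <- sgd_update(model$layers[[i]], bw$grads[[i]], vel[[i]],
                        config$learning_rate, config$momentum)
        model$layers[[i]] <- u$layer
        vel[i] <- list(u$vel)
      }
    }
    vacc <- nn_accuracy(model, xv, yv)
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                     train_acc = ep_hit / n, val_acc = vacc))
    if (vacc > best$acc + 1e-12) {
      best <- list(acc = vacc, layers = model$layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$layers <- best$layers
  model$trained <- TRUE
  model$trace <- trace
  model$best_epoch <- best$epoch
  model
}

#' @export
predict.cam_cnn <- function(object, x, type = c("prob", "class", "score"),
                            ...) {
  type <- match.arg(type)
  x <- as_batch(x)
  sc <- batch_scores(object, x)
  switch(type,
         score = sc,
         prob = softmax_rows(sc),
         class = max.col(sc, ties.method = "first") - 1L)
}

#' @export
print.cam_cnn <- function(x, ...) {
  cat("<cam_cnn> architecture:", x$architecture,
      " input:", x$input_size, "x", x$input_size,
      " classes:", x$n_classes, "\n")
  cat("  spatial layers:", paste(stage_layers(x), collapse = ", "), "\n")
  cat("  trained:", x$trained)
  if (x$trained && !is.null(x$trace))
    cat("  (best val acc ", round(max(x$trace$val_acc), 3),
        " at epoch ", x$best_epoch, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.cam_cnn <- function(object, ...) {
  np <- function(l) switch(l$type,
    conv = length(l$W) + length(l$b),
    dense = length(l$W) + length(l$b),
    res = length(l$conv1$W) + length(l$conv1$b) +
          length(l$conv2$W) + length(l$conv2$b),
    incep = length(l$b1$W) + length(l$b1$b) +
            length(l$b2$W) + length(l$b2$b),
    0L)
  d <- data.frame(layer = vapply(object$layers, `[[`, character(1), "name"),
                  type = vapply(object$layers, `[[`, character(1), "type"),
                  parameters = vapply(object$layers, np, numeric(1)))
  print(object)
  cat("  total parameters:", sum(d$parameters), "\n")
  invisible(d)
}
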