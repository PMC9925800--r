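# Class activation map methods. All methods share the same post-processing:
# the raw class-relevance map at layer resolution is passed through ReLU,
# upsampled to input resolution by bilinear interpolation, and min-max
# normalized so that heatmap values lie in [0, 1] with maximum 1 (all zeros
# when the raw map is identically zero). CAMs are computed for the damaged
# class (y = 1) by default.

upsample_bilinear <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  as.matrix(EBImage::resize(m, w = out_h, h = out_w, filter = "bilinear"))
}

normalize_heatmap <- function(m) {
  mn <- min(m); mx <- max(m)
  if (mx - mn > 0) return((m - mn) / (mx - mn))
  if (mx > 0) return(matrix(1, nrow(m), ncol(m)))
  matrix(0, nrow(m), ncol(m))
}

new_cam_heatmap <- function(values, method, model, layer, class_index, ...) {
  structure(values, class = c("cam_heatmap", "matrix"),
            method = method, model = model$architecture, layer = layer,
            class_index = class_index, ...)
}

#' @export
print.cam_heatmap <- function(x, ...) {
  cat("<cam_heatmap>", attr(x, "method"), "on", attr(x, "model"),
      "layer(s)", paste(attr(x, "layer"), collapse = "+"),
      sprintf("class %d  %dx%d  range [%.3f, %.3f]\n", attr(x, "class_index"),
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

postprocess_cam <- function(raw, model, method, layer, class_index, ...) {
  up <- upsample_bilinear(pmax(raw, 0), model$input_size, model$input_size)
  new_cam_heatmap(normalize_heatmap(up), method, model, layer, class_index, ...)
}

#' Grad-CAM
#'
#' Channel weights are the spatial global average of the pre-softmax class
#' score gradient, `w_k = mean_ij dY(c)/dA_k(i,j)`; the map is
#' `ReLU(sum_k w_k A_k)`, upsampled and normalized.
#'
#' @param model a trained [cam_cnn].
#' @param image numeric matrix in `[0, 1]` at the model's input size.
#' @param layer spatial layer name (default: deepest).
#' @param class_index class label the map explains (default 1, damaged).
#' @return a `cam_heatmap` (matrix in `[0, 1]` at input resolution).
#' @export
grad_cam <- function(model, image, layer = last_conv_layer(model),
                     class_index = 1L) {
  a <- activations(model, pixels_of(image), layer)
  g <- class_gradient(model, pixels_of(image), layer, class_index)
  k <- dim(a)[3]
  w <- colMeans(matrix(g, ncol = k))
  raw <- matrix(matrix(a, ncol = k) %*% w, dim(a)[1], dim(a)[2])
  postprocess_cam(raw, model, "gradcam", layer, class_index)
}

# Raw Grad-CAM++ alpha coefficients (closed form on the exponentialized
# pre-softmax score, valid for piecewise-linear score paths):
#   alpha_k(i,j) = g^2 / (2 g^2 + sum_ab(A_k) * g^3),  0/0 -> 0
# where g = dY(c)/dA_k(i,j).
gradcampp_alpha_raw <- function(a, g) {
  k <- dim(a)[3]
  g2 <- g^2
  g3 <- g^3
  s <- colSums(matrix(a, ncol = k))
  denom <- 2 * g2 + sweep(g3, 3, s, "*")
  alpha <- ifelse(abs(denom) < 1e-12, 0, g2 / denom)
  array(alpha, dim(a))
}

#' Grad-CAM++
#'
#' Channel weights are a weighted average of the positive class-score
#' gradients, `w_k = sum_ij alpha_k(i,j) ReLU(dY(c)/dA_k(i,j))`. The alpha
#' coefficients use the standard closed form on the exponentialized
#' pre-softmax score with `0/0 -> 0`, normalized per channel to sum to one
#' (so spatially constant gradients give `alpha = 1/(H*W)` and the weights
#' reduce to Grad-CAM's).
#'
#' @inheritParams grad_cam
#' @return a `cam_heatmap`.
#' @export
grad_cam_pp <- function(model, image, layer = last_conv_layer(model),
                        class_index = 1L) {
  a <- activations(model, pixels_of(image), layer)
  g <- class_gradient(model, pixels_of(image), layer, class_index)
  k <- dim(a)[3]
  alpha <- gradcampp_alpha_raw(a, g)
  asum <- colSums(matrix(alpha, ncol = k))
  alpha <- sweep(alpha, 3, ifelse(asum > 0, asum, 1), "/")
  w <- colSums(matrix(alpha * pmax(g, 0), ncol = k))
  raw <- matrix(matrix(a, ncol = k) %*% w, dim(a)[1], dim(a)[2])
  postprocess_cam(raw, model, "gradcampp", layer, class_index)
}

scorecam_channel_weights <- function(model, image, a, class_index,
                                     channels = seq_len(dim(a)[3])) {
  px <- pixels_of(image)
  masks <- lapply(channels, function(k) {
    up <- upsample_bilinear(a[, , k], nrow(px), ncol(px))
    rng <- max(up) - min(up)
    if (rng > 0) (up - min(up)) / rng else matrix(0, nrow(px), ncol(px))
  })
  sc <- masked_scores(model, px, masks)[, class_index + 1L]
  e <- exp(sc - max(sc))
  e / sum(e)
}

#' Score-CAM
#'
#' Gradient-free channel weighting: each activation map is upsampled to
#' input resolution, min-max normalized to `[0, 1]`, used to mask the input
#' image, and the pre-softmax class scores of the masked images are passed
#' through a softmax over channels to give the weights. The map is
#' `ReLU(sum_k w_k A_k)`, upsampled and normalized.
#'
#' @inheritParams grad_cam
#' @return a `cam_heatmap`. The channel weights (a probability vector over
#'   channels) are attached as attribute `weights`.
#' @export
score_cam <- function(model, image, layer = last_conv_layer(model),
                      class_index = 1L) {
  a <- activations(model, pixels_of(image), layer)
  k <- dim(a)[3]
  w <- scorecam_channel_weights(model, image, a, class_index)
  raw <- matrix(matrix(a, ncol = k) %*% w, dim(a)[1], dim(a)[2])
  postprocess_cam(raw, model, "scorecam", layer, class_index, weights = w)
}

#' Faster Score-CAM
#'
#' Score-CAM restricted to the `top_n` channels with the largest spatial
#' variance of their activation map (descending, ties broken by the lower
#' channel index); the softmax runs over the retained channels only. With
#' `K <= top_n` channels the result is identical to [score_cam()].
#'
#' @inheritParams grad_cam
#' @param top_n number of high-variance channels to retain (default 10).
#' @return a `cam_heatmap` with attributes `weights` and `channels`.
#' @export
faster_score_cam <- function(model, image, layer = last_conv_layer(model),
                             class_index = 1L, top_n = 10L) {
  a <- activations(model, pixels_of(image), layer)
  k <- dim(a)[3]
  v <- apply(matrix(a, ncol = k), 2, var)
  keep <- order(-v, seq_len(k))[seq_len(min(top_n, k))]
  w <- scorecam_channel_weights(model, image, a, class_index, keep)
  raw <- matrix(matrix(a[, , keep, drop = FALSE], ncol = length(keep)) %*% w,
                dim(a)[1], dim(a)[2])
  postprocess_cam(raw, model, "faster_scorecam", layer, class_index,
                  weights = w, channels = keep)
}

#' Layer-CAM
#'
#' Multi-layer CAM with per-location weights. For each layer the gradient's
#' deviation from its spatial mean (mode `"deviation"`) or the raw gradient
#' (mode `"classic"`) is rectified into location weights
#' `w_k(x,y) = ReLU(g_k(x,y))`, multiplied element-wise with the activation
#' maps, summed over channels and rectified:
#' `M = ReLU(sum_k w_k A_k)`. Each layer's map is rescaled by
#' `tanh(gamma * M / max(M))` (all-zero layers contribute zeros), upsampled
#' to input resolution, and the layers are fused element-wise (maximum by
#' default, configurable to mean). The fused map is then min-max normalized.
#'
#' @inheritParams grad_cam
#' @param layers ordered (shallow to deep) character vector of layer names;
#'   defaults to the last spatial layer of every resolution stage.
#' @param gamma rescaling factor (default 2).
#' @param mode `"deviation"` (gradient deviation from its spatial mean) or
#'   `"classic"` (raw gradient).
#' @param fusion `"max"` or `"mean"` across layers.
#' @return a `cam_heatmap`; attribute `prenorm_max` holds the fused map's
#'   maximum before the final normalization (equal to `tanh(gamma)` whenever
#'   any layer map is non-zero and fusion is `"max"`).
#' @export
layer_cam <- function(model, image, layers = stage_layers(model),
                      class_index = 1L, gamma = 2,
                      mode = c("deviation", "classic"),
                      fusion = c("max", "mean")) {
  mode <- match.arg(mode)
  fusion <- match.arg(fusion)
  stopifnot(length(layers) >= 1)
  px <- pixels_of(image)
  layer_max <- numeric(length(layers))
  maps <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[i]
    a <- activations(model, px, ly)
    g <- class_gradient(model, px, ly, class_index)
    k <- dim(a)[3]
    if (mode == "deviation") {
      gbar <- colMeans(matrix(g, ncol = k))
      g <- sweep(g, 3, gbar, "-")
    }
    wloc <- pmax(g, 0)
    m <- matrix(rowSums(matrix(wloc * a, ncol = k)), dim(a)[1], dim(a)[2])
    m <- pmax(m, 0)
    mx <- max(m)
    m <- if (mx > 0) tanh(gamma * m / mx) else m
    layer_max[i] <- max(m)
    maps[[i]] <- upsample_bilinear(m, model$input_size, model$input_size)
  }
  fused <- Reduce(if (fusion == "max") pmax else `+`, maps)
  if (fusion == "mean") fused <- fused / length(maps)
  new_cam_heatmap(normalize_heatmap(fused), "layercam", model, layers,
                  class_index, prenorm_max = max(layer_max))
}

#' Registry of CAM methods
#'
#' `cam_methods()` lists the available method tags; `compute_cam()`
#' dispatches a tag to the corresponding method with its default arguments.
#'
#' @param method one of `"gradcam"`, `"gradcampp"`, `"scorecam"`,
#'   `"faster_scorecam"`, `"layercam"`.
#' @inheritParams grad_cam
#' @param ... passed to the method.
#' @return `compute_cam()`: a `cam_heatmap`.
#' @export
cam_methods <- function() {
  c("gradcam", "gradcampp", "scorecam", "faster_scorecam", "layercam")
}

#' @rdname cam_methods
#' @export
compute_cam <- function(method, model, image, class_index = 1L, ...) {
  method <- match.arg(method, cam_methods())
  switch(method,
         gradcam = grad_cam(model, image, class_index = class_index, ...),
         gradcampp = grad_cam_pp(model, image, class_index = class_index, ...),
         scorecam = score_cam(model, image, class_index = class_index, ...),
         faster_scorecam = faster_score_cam(model, image,
                                            class_index = class_index, ...),
         layercam = layer_cam(model, image, class_index = class_index, ...))
}

#' Binarize a heatmap into a damage mask
#'
#' Thresholds a normalized `[0, 1]` heatmap at `t_cam`: pixels with value
#' `>= t_cam` (or `> t_cam` when `strict`) are damaged. When a foreground
#' mask is supplied the damage mask is restricted to it.
#'
#' @param heatmap a `cam_heatmap` or numeric matrix in `[0, 1]`.
#' @param t_cam threshold in the open interval (0, 1).
#' @param foreground optional logical matrix restricting the mask.
#' @param strict use `>` instead of the default `>=`.
#' @return logical matrix, `TRUE` = damaged.
#' @export
binarize <- function(heatmap, t_cam, foreground = NULL, strict = FALSE) {
  if (t_cam <= 0 || t_cam >= 1) stop("t_cam must lie in (0, 1)")
  m <- unclass(heatmap)
  attributes(m) <- list(dim = dim(heatmap))
  mask <- if (strict) m > t_cam else m >= t_cam
  if (!is.null(foreground)) {
    stopifnot(identical(dim(foreground), dim(mask)))
    mask <- mask & foreground
  }
  mask
}
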