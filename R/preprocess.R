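# Background/foreground separation, augmentation, leakage-free splits.

pixels_of <- function(image) {
  if (inherits(image, "slice_image")) image$pixels else image
}

# 3x3 grayscale max/min filters via shifted pmax/pmin (replicated borders).
shift_pad <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- pmin(pmax(seq_len(n1) + di, 1L), n1)
  rj <- pmin(pmax(seq_len(n2) + dj, 1L), n2)
  m[ri, rj, drop = FALSE]
}

rank_filter <- function(m, size, fun) {
  r <- (size - 1L) %/% 2L
  out <- m
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    out <- fun(out, shift_pad(m, di, dj))
  }
  out
}

#' Foreground mask by filtering and 2-cluster k-means
#'
#' Separates tissue foreground from background: the image is converted to
#' 8-bit, a max filter, an erosion (min filter) and a Gaussian blur are
#' applied to suppress background artifacts, then pixel intensities are
#' clustered with k-means (k = 2, deterministically initialised from the two
#' intensity extremes) and the cluster with the higher mean intensity is
#' labelled foreground.
#'
#' @param image a [slice_image] or numeric matrix in `[0, 1]`.
#' @param max_size,erode_size square structuring-element sizes (default 7;
#'   equal sizes make the max/erode pair a grayscale closing that fills dark
#'   texture holes without moving the tissue boundary).
#' @param sigma Gaussian blur s.d. in pixels (default 0.5).
#' @return logical matrix, `TRUE` = foreground.
#' @export
foreground_mask <- function(image, max_size = 7L, erode_size = 7L,
                            sigma = 0.5) {
  px <- pixels_of(image)
  stopifnot(is.matrix(px))
  img8 <- round(255 * clip01(px))
  f <- rank_filter(img8, max_size, pmax)
  f <- rank_filter(f, erode_size, pmin)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  v <- as.vector(f)
  if (max(v) - min(v) < 1e-8)
    stop("degenerate clustering: image is constant after filtering")
  km <- kmeans(v, centers = matrix(c(min(v), max(v)), 2, 1))
  fg_cluster <- which.max(km$centers)
  matrix(km$cluster == fg_cluster, nrow(px), ncol(px))
}

# -- augmentation -----------------------------------------------------------

flip_h <- function(m) m[nrow(m):1, , drop = FALSE]
flip_v <- function(m) m[, ncol(m):1, drop = FALSE]

shift_image <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  ok_i <- si >= 1 & si <= nrow(m)
  ok_j <- sj >= 1 & sj <= ncol(m)
  out[which(ok_i), which(ok_j)] <- m[si[ok_i], sj[ok_j]]
  out
}

rotate_image <- function(m, angle) {
  if (angle == 0) return(m)
  r <- EBImage::rotate(m, angle, filter = "bilinear",
                       output.dim = dim(m), bg.col = 0)
  clip01(as.matrix(r))
}

#' Contrast enhancement transforms
#'
#' `contrast_stretch()` linearly rescales the 2nd..98th intensity
#' percentiles to `[0, 1]`; `hist_equalize()` applies global histogram
#' equalization; `clahe_enhance()` applies contrast-limited adaptive
#' histogram equalization.
#'
#' @param m numeric matrix in `[0, 1]`.
#' @param lower,upper percentile bounds for stretching.
#' @param nx,limit CLAHE tile count per side and clip limit.
#' @return numeric matrix in `[0, 1]`.
#' @export
contrast_stretch <- function(m, lower = 0.02, upper = 0.98) {
  q <- quantile(m, c(lower, upper), names = FALSE)
  if (q[2] - q[1] < 1e-12) return(m)
  clip01((m - q[1]) / (q[2] - q[1]))
}

#' @rdname contrast_stretch
#' @export
hist_equalize <- function(m) {
  clip01(as.matrix(EBImage::equalize(m, range = c(0, 1), levels = 256)))
}

#' @rdname contrast_stretch
#' @export
clahe_enhance <- function(m, nx = 8, limit = 2) {
  clip01(as.matrix(EBImage::clahe(m, nx = nx, limit = limit)))
}

#' Augmentation configuration
#'
#' @param rotation maximum absolute rotation angle in degrees (default 45).
#' @param shift maximum shift as a fraction of the image side (default 0.2).
#' @param flips include horizontal and vertical flips.
#' @param contrast include the three contrast-enhanced variants (stretching,
#'   histogram equalization, CLAHE).
#' @return list of class `augment_config`.
#' @export
augment_config <- function(rotation = 45, shift = 0.2, flips = TRUE,
                           contrast = TRUE) {
  stopifnot(rotation >= 0, shift >= 0, shift <= 1)
  structure(list(rotation = rotation, shift = shift, flips = isTRUE(flips),
                 contrast = isTRUE(contrast)),
            class = "augment_config")
}

#' Augment a training image
#'
#' Emits independent augmented copies of one slice: a random rotation in
#' `[-rotation, rotation]` degrees, horizontal and vertical flips, a random
#' width/height shift of up to `shift` of the image side (constant-zero
#' fill, matching background-removed images), and the three contrast
#' enhancements. Class label and sample identity are preserved. Randomness
#' uses the caller's RNG state.
#'
#' @param image a [slice_image] or numeric matrix.
#' @param config an [augment_config()].
#' @return list of augmented images (same type as the input), each tagged
#'   with a `transform` attribute.
#' @export
augment <- function(image, config = augment_config()) {
  px <- pixels_of(image)
  out <- list()
  add <- function(m, tag) {
    r <- if (inherits(image, "slice_image")) {
      im <- image; im$pixels <- m; im
    } else m
    attr(r, "transform") <- tag
    out[[length(out) + 1L]] <<- r
  }
  add(rotate_image(px, runif(1, -config$rotation, config$rotation)), "rotation")
  if (config$flips) {
    add(flip_h(px), "hflip")
    add(flip_v(px), "vflip")
  }
  di <- round(runif(1, -config$shift, config$shift) * nrow(px))
  dj <- round(runif(1, -config$shift, config$shift) * ncol(px))
  add(shift_image(px, di, dj), "shift")
  if (config$contrast) {
    add(contrast_stretch(px), "contrast_stretch")
    add(hist_equalize(px), "hist_equalize")
    add(clahe_enhance(px), "clahe")
  }
  out
}

# -- splitting --------------------------------------------------------------

#' Leakage-free sample-level split
#'
#' Randomly assigns whole samples to train/validation/test partitions so
#' that no sample contributes slices to more than one partition. Partition
#' sizes follow the requested fractions (largest-remainder rounding, at
#' least one sample per partition).
#'
#' @param samples a `synthetic_dataset`, a list of objects with
#'   `$sample_id`, or a character vector of sample ids (>= 3 ids).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @return data frame with columns `sample_id` and `partition`
#'   (class `split_assignment`).
#' @export
split_by_sample <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  ids <- if (is.character(samples)) samples
         else vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  n <- length(ids)
  if (n < 3) stop("need at least 3 samples to split")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three values summing to 1")
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    order_frac <- order(raw - cnt, decreasing = TRUE)
    cnt[order_frac[seq_len(rem)]] <- cnt[order_frac[seq_len(rem)]] + 1
  }
  # every partition gets at least one sample
  while (any(cnt == 0)) {
    cnt[which.max(cnt)] <- max(cnt) - 1
    cnt[which(cnt == 0)[1]] <- 1
  }
  set.seed(seed)
  perm <- sample(ids)
  part <- rep(c("train", "val", "test"), times = cnt)
  out <- data.frame(sample_id = perm, partition = part,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$sample_id, ids)), ]
  rownames(out) <- NULL
  class(out) <- c("split_assignment", "data.frame")
  out
}

partition_ids <- function(split, partition) {
  split$sample_id[split$partition == partition]
}

#' Assemble training tensors from a dataset and a split
#'
#' Flattens a `synthetic_dataset` into the `train`/`val`/`test` arrays the
#' classifier consumes (H x W x 1 x N with labels 0/1), optionally
#' augmenting the training partition with [augment()].
#'
#' @param dataset a [generate_dataset()] result.
#' @param split a [split_by_sample()] assignment.
#' @param augment_train logical; augment the training partition.
#' @param augment_cfg an [augment_config()].
#' @param seed seed for the augmentation RNG.
#' @return list with `train`, `val`, `test`, each a list of `x`, `y`,
#'   `sample_id`, `slice_index`.
#' @export
dataset_tensors <- function(dataset, split, augment_train = FALSE,
                            augment_cfg = augment_config(), seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  n <- attr(dataset, "config")$image_size
  gather <- function(part) {
    ids <- partition_ids(split, part)
    slices <- list()
    for (s in dataset) {
      if (!(s$sample_id %in% ids)) next
      slices <- c(slices, s$fresh_slices, s$damaged_slices)
    }
    slices
  }
  pack <- function(slices) {
    x <- array(0, c(n, n, 1L, length(slices)))
    for (i in seq_along(slices)) x[, , 1L, i] <- slices[[i]]$pixels
    list(x = x,
         y = vapply(slices, `[[`, integer(1), "y"),
         sample_id = vapply(slices, `[[`, character(1), "sample_id"),
         slice_index = vapply(slices, `[[`, integer(1), "slice_index"))
  }
  tr <- gather("train")
  if (augment_train && length(tr)) {
    set.seed(seed)
    aug <- list()
    for (sl in tr) aug <- c(aug, augment(sl, augment_cfg))
    tr <- c(tr, aug)
  }
  list(train = pack(tr), val = pack(gather("val")),
       test = pack(gather("test")))
}
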