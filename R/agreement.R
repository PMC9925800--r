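# IoU-based agreement statistics and the nonparametric test wrappers.

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  stopifnot(all(m %in% c(0, 1)))
  m > 0
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the ratio is
#' 0/0; by convention this is perfect agreement on "no damage" and returns
#' `both_empty` (default 1; set `NA` to flag such pairs for exclusion).
#'
#' @param a,b logical (or 0/1) matrices of equal shape.
#' @param both_empty value returned when both masks are empty.
#' @return fraction in `[0, 1]` (or `both_empty`).
#' @examples
#' iou(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'     matrix(c(FALSE, TRUE, FALSE, TRUE), 2))  # 1/3
#' @export
iou <- function(a, b, both_empty = 1) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- as_mask(a); b <- as_mask(b)
  u <- sum(a | b)
  if (u == 0) return(both_empty)
  sum(a & b) / u
}

#' Mean IoU over paired slices
#'
#' Arithmetic mean of the per-slice IoU of two paired mask lists.
#'
#' @param a_slices,b_slices lists of masks of equal length (>= 1), paired by
#'   position.
#' @inheritParams iou
#' @return fraction in `[0, 1]`.
#' @export
mean_iou <- function(a_slices, b_slices, both_empty = 1) {
  if (length(a_slices) != length(b_slices) || length(a_slices) == 0)
    stop("mask lists must be paired and non-empty")
  mean(mapply(iou, a_slices, b_slices,
              MoreArgs = list(both_empty = both_empty)))
}

pairwise_mean_iou <- function(masks, both_empty = 1) {
  n <- length(masks)
  pairs <- utils::combn(n, 2)
  vals <- apply(pairs, 2, function(p)
    iou(masks[[p[1]]], masks[[p[2]]], both_empty = both_empty))
  vals <- vals[!is.na(vals)]
  list(value = if (length(vals)) mean(vals) else NA_real_,
       n_pairs = length(vals))
}

agreement_record <- function(value, n_pairs, axis_type, axis, t_cam, slice) {
  structure(data.frame(slice = slice, axis_type = axis_type, axis = axis,
                       t_cam = t_cam, value = value, n_pairs = n_pairs,
                       stringsAsFactors = FALSE),
            class = c("agreement_record", "data.frame"))
}

#' Agreement across CAM methods (model fixed)
#'
#' Mean IoU over all unordered pairs of CAM methods applied to the same
#' slice with the same CNN model and threshold: the cross-method agreement
#' of one slice. With `|C|` methods the mean runs over `choose(|C|, 2)`
#' pairs.
#'
#' @param masks_by_method named list (>= 2) of equal-shape binary masks, one
#'   per CAM method.
#' @param model identifier of the fixed model axis.
#' @param t_cam threshold at which the masks were binarized.
#' @param slice slice identifier.
#' @inheritParams iou
#' @return one-row data frame (`agreement_record`) with the mean pairwise
#'   IoU in `value` and the number of pairs averaged in `n_pairs`.
#' @export
agreement_across_cams <- function(masks_by_method, model = NA, t_cam = NA,
                                  slice = NA, both_empty = 1) {
  if (length(masks_by_method) < 2) stop("need at least 2 CAM methods")
  p <- pairwise_mean_iou(masks_by_method, both_empty)
  agreement_record(p$value, p$n_pairs, "model", model, t_cam, slice)
}

#' Agreement across CNN models (CAM method fixed)
#'
#' Mean IoU over all unordered pairs of CNN models for the same CAM method,
#' slice and threshold; the cross-model counterpart of
#' [agreement_across_cams()].
#'
#' @param masks_by_model named list (>= 2) of equal-shape binary masks, one
#'   per CNN model.
#' @param method identifier of the fixed CAM-method axis.
#' @inheritParams agreement_across_cams
#' @return one-row `agreement_record` data frame.
#' @export
agreement_across_models <- function(masks_by_model, method = NA, t_cam = NA,
                                    slice = NA, both_empty = 1) {
  if (length(masks_by_model) < 2) stop("need at least 2 CNN models")
  p <- pairwise_mean_iou(masks_by_model, both_empty)
  agreement_record(p$value, p$n_pairs, "method", method, t_cam, slice)
}

#' Damaged fraction of the foreground
#'
#' `|mask intersect foreground| / |foreground|` -- the per-slice share of
#' tissue flagged as damaged.
#'
#' @param mask binary damage mask.
#' @param foreground binary foreground mask (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
damage_fraction <- function(mask, foreground) {
  if (!identical(dim(mask), dim(foreground))) stop("mask shapes differ")
  mask <- as_mask(mask); foreground <- as_mask(foreground)
  nf <- sum(foreground)
  if (nf == 0) stop("empty foreground")
  sum(mask & foreground) / nf
}

#' Correlate per-sample damage with liquid loss
#'
#' Spearman's rank correlation between a per-sample damage score (e.g. the
#' mean CAM damage fraction over a sample's slices) and the liquid-loss
#' percentage. A Shapiro-Wilk normality check of both inputs is computed
#' and attached for logging, but the reported coefficient is always
#' Spearman's (rank-based, no normality assumption).
#'
#' @param per_sample_damage numeric vector of fractions.
#' @param ll numeric vector of liquid-loss percentages, paired.
#' @return list of class `correlation_result` with `rho`, `p_value`, `n`,
#'   `method`, `constant_input` flag, and `shapiro` p-values.
#' @export
correlate_with_liquid_loss <- function(per_sample_damage, ll) {
  if (length(per_sample_damage) != length(ll)) stop("inputs must be paired")
  n <- length(ll)
  if (n < 3) stop("need at least 3 samples")
  constant <- sd(per_sample_damage) == 0 || sd(ll) == 0
  sw <- function(v) {
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000)
      return(NA_real_)
    tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  if (constant) {
    res <- list(rho = NA_real_, p_value = NA_real_)
    warning("constant input: Spearman's rho is undefined")
  } else {
    ct <- suppressWarnings(cor.test(per_sample_damage, ll,
                                    method = "spearman", exact = FALSE))
    res <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  structure(list(rho = res$rho, p_value = res$p_value, n = n,
                 method = "spearman", constant_input = constant,
                 shapiro = c(damage = sw(per_sample_damage), ll = sw(ll))),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Kruskal-Wallis comparison of score groups
#'
#' Rank-based H test (with tie correction, as implemented in
#' [stats::kruskal.test()]) for a difference in score distributions across
#' groups.
#'
#' @param values_by_group named list (>= 2 groups) of numeric vectors
#'   (>= 2 values each).
#' @return list with `H`, `df` and `p_value`.
#' @export
compare_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2)
    stop("need at least 2 groups")
  if (any(vapply(values_by_group, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  kt <- kruskal.test(values_by_group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Area-matched random mask baseline
#'
#' Uniformly samples `n_pixels` foreground pixels into a mask; used as the
#' chance-level reference when judging CAM-versus-truth overlap.
#'
#' @param n_pixels mask area in pixels (capped at the foreground size).
#' @param foreground logical foreground matrix.
#' @return logical matrix.
#' @export
random_mask <- function(n_pixels, foreground) {
  foreground <- as_mask(foreground)
  idx <- which(foreground)
  n_pixels <- min(n_pixels, length(idx))
  out <- matrix(FALSE, nrow(foreground), ncol(foreground))
  if (n_pixels > 0) out[sample(idx, n_pixels)] <- TRUE
  out
}
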