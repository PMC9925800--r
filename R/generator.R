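#' Generator configuration
#'
#' Parameters of the synthetic image-stack generator. The generator emulates
#' the statistical structure of a freeze-damage imaging study on fish
#' fillets: paired grayscale slice stacks per sample (fresh, class `y = 0`,
#' and the same slices after a damage perturbation, class `y = 1`), an
#' elliptical tissue foreground on a dark background, a spatially smooth
#' damage field without hard boundaries (heaviest toward the slice centre),
#' per-slice ground-truth damage masks, and a per-sample liquid-loss
#' percentage coupled to the realised damage fraction.
#'
#' @param image_size pixels per side (square slices), at least 32.
#' @param n_samples_per_group number of samples in each treatment group;
#'   scalar or one count per treatment level. Defaults to the 11/11/10 group
#'   sizes of a three-temperature freezing protocol (32 samples).
#' @param slices_per_sample slices per sample (default 8).
#' @param treatment_levels strictly ordered severity scalars in `[0, 1]`,
#'   high to low, emulating freezing at -5, -20 and -40 degrees C
#'   (slow freezing damages most).
#' @param texture_params list with `corr_len` (correlation length, px) and
#'   `amplitude` of the shared base texture.
#' @param damage_field_smoothness correlation length (px) of the damage
#'   field; larger values give softer mask boundaries.
#' @param center_bias weight (>= 0) biasing damage toward the slice centre.
#' @param ll_coupling list with `base` (percent at zero damage), `slope`
#'   (percent per unit damage fraction) and `noise_sd` (percent) linking the
#'   damage fraction to liquid loss.
#' @param damage_amplitude list with `add` and `mult` components of the
#'   texture perturbation applied inside the damage mask (scaled by
#'   severity).
#' @param noise_sd acquisition noise s.d. added independently to fresh and
#'   damaged slices.
#' @param quantize_12bit quantize intensities to 4096 gray levels (emulating
#'   12-bit acquisition).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(image_size = 64,
                             n_samples_per_group = c(11L, 11L, 10L),
                             slices_per_sample = 8L,
                             treatment_levels = c(0.9, 0.5, 0.1),
                             texture_params = list(corr_len = 4, amplitude = 0.10),
                             damage_field_smoothness = 9,
                             center_bias = 1.5,
                             ll_coupling = list(base = 2, slope = 20, noise_sd = 1.5),
                             damage_amplitude = list(add = 0.20, mult = 0.30),
                             noise_sd = 0.01,
                             quantize_12bit = TRUE,
                             seed = 1L) {
  if (image_size < 32) stop("image_size must be >= 32")
  if (image_size %% 4 != 0) stop("image_size must be a multiple of 4")
  if (slices_per_sample < 1) stop("slices_per_sample must be >= 1")
  if (any(treatment_levels < 0 | treatment_levels > 1))
    stop("treatment severities must lie in [0, 1]")
  if (length(treatment_levels) > 1) {
    d <- diff(treatment_levels)
    if (!(all(d > 0) || all(d < 0)))
      stop("treatment_levels must be strictly ordered")
  }
  if (length(n_samples_per_group) == 1)
    n_samples_per_group <- rep(n_samples_per_group, length(treatment_levels))
  if (length(n_samples_per_group) != length(treatment_levels))
    stop("n_samples_per_group must match treatment_levels")
  if (ll_coupling$noise_sd < 0) stop("ll_coupling$noise_sd must be >= 0")
  if (center_bias < 0) stop("center_bias must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 slices_per_sample = as.integer(slices_per_sample),
                 treatment_levels = treatment_levels,
                 texture_params = texture_params,
                 damage_field_smoothness = damage_field_smoothness,
                 center_bias = center_bias,
                 ll_coupling = ll_coupling,
                 damage_amplitude = damage_amplitude,
                 noise_sd = noise_sd,
                 quantize_12bit = isTRUE(quantize_12bit),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Periodic Gaussian smoothing by FFT; works for any sigma relative to the
# image size (unlike kernel convolution, which needs kernel < image).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  d1 <- pmin(0:(n1 - 1), n1 - 0:(n1 - 1))
  d2 <- pmin(0:(n2 - 1), n2 - 0:(n2 - 1))
  k <- exp(-outer(d1^2, d2^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (n1 * n2)
}

# Standardized smooth Gaussian random field.
grf <- function(n, sigma) {
  s <- smooth_field(matrix(rnorm(n * n), n, n), sigma)
  (s - mean(s)) / sd(s)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

quantize12 <- function(x) round(x * 4095) / 4095

#' One grayscale slice with its metadata
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param sample_id sample identifier.
#' @param slice_index slice number within the sample.
#' @param y class label: 0 fresh, 1 damaged.
#' @param treatment treatment severity of the sample.
#' @return list of class `slice_image`.
#' @export
slice_image <- function(pixels, sample_id, slice_index, y, treatment) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, sample_id = sample_id,
                 slice_index = as.integer(slice_index), y = as.integer(y),
                 treatment = treatment),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat("<slice_image> sample", x$sample_id, "slice", x$slice_index,
      "y =", x$y, "treatment", x$treatment,
      sprintf("(%dx%d)\n", nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Generate a synthetic freeze-damage dataset
#'
#' Produces paired fresh/damaged slice stacks with known per-pixel damage
#' masks. For every sample an elliptical foreground is drawn on a dark
#' background and filled with a shared smooth base texture; the damaged
#' slices are the fresh slices with a smooth texture perturbation applied
#' inside the ground-truth mask, its magnitude proportional to treatment
#' severity. The mask is obtained by thresholding a smooth Gaussian random
#' field combined with a radial centre bias, so the mask boundary is soft by
#' construction. A liquid-loss percentage is drawn per sample via
#' [simulate_liquid_loss()].
#'
#' @param config a [generator_config()].
#' @return list of `synthetic_sample` objects (class `synthetic_dataset`).
#'   Each sample holds `fresh_slices`, `damaged_slices`, `truth_masks`,
#'   `foreground` (per-slice masks), `damage_field` (the continuous field,
#'   for diagnostics), `damage_fraction` and `liquid_loss_pct`.
#' @examples
#' ds <- generate_dataset(generator_config(n_samples_per_group = 1,
#'                                         slices_per_sample = 2, seed = 7))
#' ds[[1]]
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$image_size
  samples <- list()
  sid <- 0L
  for (g in seq_along(config$treatment_levels)) {
    sev <- config$treatment_levels[g]
    for (r in seq_len(config$n_samples_per_group[g])) {
      sid <- sid + 1L
      samples[[sid]] <- generate_sample(config, sprintf("S%02d", sid), g, sev)
    }
  }
  structure(samples, class = "synthetic_dataset", config = config)
}

generate_sample <- function(config, sample_id, group, severity) {
  n <- config$image_size
  ns <- config$slices_per_sample
  # sample-level geometry: ellipse centre, axes, orientation
  cx <- n / 2 + runif(1, -0.04, 0.04) * n
  cy <- n / 2 + runif(1, -0.04, 0.04) * n
  ax <- n * runif(1, 0.34, 0.42)
  bx <- n * runif(1, 0.26, 0.34)
  th <- runif(1, 0, pi)
  # sample-level damage extent (biological between-sample variability)
  fbase <- rbeta(1, 6, 3)
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  u <- (ii - cx) * cos(th) + (jj - cy) * sin(th)
  v <- -(ii - cx) * sin(th) + (jj - cy) * cos(th)

  fresh <- damaged <- masks <- fgs <- fields <- vector("list", ns)
  frac <- numeric(ns)
  for (s in seq_len(ns)) {
    scale <- runif(1, 0.97, 1.03)               # slice-to-slice girth change
    rho2 <- (u / (ax * scale))^2 + (v / (bx * scale))^2
    fg <- rho2 <= 1
    base <- 0.06 + 0.49 * fg +
      config$texture_params$amplitude * grf(n, config$texture_params$corr_len) * fg
    # smooth damage field: random field plus radial centre bias
    field_raw <- grf(n, config$damage_field_smoothness) +
      config$center_bias * (1 - pmin(rho2, 1))
    f_target <- clip01(severity * (fbase + rnorm(1, 0, 0.05)))
    f_target <- min(f_target, 0.95)
    if (f_target > 0 && any(fg)) {
      thr <- quantile(field_raw[fg], 1 - f_target, names = FALSE)
      mask <- fg & (field_raw >= thr)
      # soft edge taper: the perturbation holds its full amplitude over the
      # mask interior and falls smoothly to 0 at the mask boundary (outer
      # ~30% of the within-mask field range), so the truth mask stays
      # identifiable from the pixels while its boundary remains soft
      knee <- quantile(field_raw[mask], 0.3, names = FALSE)
      ramp <- if (knee > thr) pmin(pmax((field_raw - thr) / (knee - thr), 0), 1)
              else (field_raw >= thr) * 1
    } else {
      mask <- fg & FALSE
      ramp <- matrix(0, n, n)
    }
    perturb <- grf(n, 2.5)
    delta <- severity * ramp *
      (config$damage_amplitude$add + config$damage_amplitude$mult * perturb)
    delta[!mask] <- 0
    fresh_px <- clip01(base + rnorm(n * n, 0, config$noise_sd))
    dam_px <- clip01(base + delta + rnorm(n * n, 0, config$noise_sd))
    if (config$quantize_12bit) {
      fresh_px <- quantize12(fresh_px)
      dam_px <- quantize12(dam_px)
    }
    fresh[[s]] <- slice_image(fresh_px, sample_id, s, 0L, severity)
    damaged[[s]] <- slice_image(dam_px, sample_id, s, 1L, severity)
    masks[[s]] <- mask
    fgs[[s]] <- fg
    fields[[s]] <- field_raw
    frac[s] <- if (any(fg)) sum(mask) / sum(fg) else 0
  }
  df <- mean(frac)
  ll <- simulate_liquid_loss(df, config$ll_coupling)
  structure(list(sample_id = sample_id, group = group,
                 treatment_level = severity,
                 fresh_slices = fresh, damaged_slices = damaged,
                 truth_masks = masks, foreground = fgs,
                 damage_field = fields,
                 slice_damage_fraction = frac,
                 damage_fraction = df, liquid_loss_pct = ll),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("<synthetic_sample>", x$sample_id,
      " severity", x$treatment_level,
      " slices", length(x$fresh_slices),
      sprintf(" damage %.2f  liquid loss %.1f%%\n",
              x$damage_fraction, x$liquid_loss_pct))
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<synthetic_dataset>", length(x), "samples,",
      cfg$slices_per_sample, "slices each,",
      cfg$image_size, "x", cfg$image_size, "\n")
  cat("  severities:", paste(cfg$treatment_levels, collapse = ", "),
      " groups:", paste(cfg$n_samples_per_group, collapse = "/"), "\n")
  invisible(x)
}

#' Simulate liquid loss from a damage fraction
#'
#' Liquid loss is modelled as an affine function of the damage fraction plus
#' Gaussian noise, clipped to `[0, 100]` percent: more tissue damage expels
#' more liquid.
#'
#' @param damage_fraction fraction(s) in `[0, 1]`.
#' @param coupling list with `base`, `slope` and `noise_sd` (percent units).
#' @return percent value(s) in `[0, 100]`.
#' @examples
#' simulate_liquid_loss(0.5, list(base = 2, slope = 20, noise_sd = 0))
#' @export
simulate_liquid_loss <- function(damage_fraction,
                                 coupling = list(base = 2, slope = 20,
                                                 noise_sd = 1.5)) {
  if (any(damage_fraction < 0 | damage_fraction > 1))
    stop("damage_fraction must lie in [0, 1]")
  if (coupling$noise_sd < 0) stop("coupling$noise_sd must be >= 0")
  ll <- coupling$base + coupling$slope * damage_fraction +
    rnorm(length(damage_fraction), 0, coupling$noise_sd)
  pmin(pmax(ll, 0), 100)
}

#' Liquid loss from sample masses
#'
#' Percent mass lost between the initial mass and the mass after the
#' freeze-thaw protocol: `100 * (m0 - mL) / m0`.
#'
#' @param m0 initial mass (g), positive.
#' @param mL final mass (g), `0 <= mL <= m0`.
#' @return percent in `[0, 100]`.
#' @examples
#' liquid_loss_percent(150, 135)  # 10
#' @export
liquid_loss_percent <- function(m0, mL) {
  if (any(m0 <= 0)) stop("m0 must be positive")
  if (any(mL < 0) || any(mL > m0)) stop("mL must satisfy 0 <= mL <= m0")
  100 * (m0 - mL) / m0
}

#' Export a synthetic dataset to disk
#'
#' Writes per-slice PNG images (16-bit grayscale) for the fresh and damaged
#' stacks and the truth masks, a per-sample metadata CSV and a JSON sidecar
#' with the generator configuration.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(sample_id = character(0))
  for (s in dataset) {
    for (i in seq_along(s$fresh_slices)) {
      png::writePNG(s$fresh_slices[[i]]$pixels,
                    file.path(dir, sprintf("%s_%02d_fresh.png", s$sample_id, i)))
      png::writePNG(s$damaged_slices[[i]]$pixels,
                    file.path(dir, sprintf("%s_%02d_damaged.png", s$sample_id, i)))
      png::writePNG(s$truth_masks[[i]] * 1,
                    file.path(dir, sprintf("%s_%02d_mask.png", s$sample_id, i)))
    }
  }
  meta <- do.call(rbind, lapply(dataset, function(s)
    data.frame(sample_id = s$sample_id, group = s$group,
               treatment_level = s$treatment_level,
               n_slices = length(s$fresh_slices),
               damage_fraction = s$damage_fraction,
               liquid_loss_pct = s$liquid_loss_pct)))
  write.csv(meta, file.path(dir, "samples.csv"), row.names = FALSE)
  cfg <- attr(dataset, "config")
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
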