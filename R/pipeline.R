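# End-to-end orchestration: generate -> preprocess/split -> train ->
# CAMs for y = 1 -> binarize over the t_CAM grid -> agreement statistics.

#' Pipeline configuration
#'
#' @param generator a [generator_config()].
#' @param architectures character vector of [cam_cnn] architectures to
#'   train (>= 2 for cross-model agreement).
#' @param methods CAM method tags (>= 2 for cross-method agreement); see
#'   [cam_methods()].
#' @param t_grid thresholds for binarization, all in (0, 1).
#' @param train a [train_config()].
#' @param split_fractions train/val/test sample fractions.
#' @param augment_train augment the training partition.
#' @param t_reference threshold used for the liquid-loss correlation and
#'   the group tests (default 0.5).
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       architectures = cam_cnn_architectures(),
                       methods = cam_methods(),
                       t_grid = seq(0.1, 0.9, by = 0.1),
                       train = train_config(),
                       split_fractions = c(0.8, 0.1, 0.1),
                       augment_train = TRUE,
                       t_reference = 0.5,
                       seed = 1L) {
  stopifnot(length(architectures) >= 1, length(methods) >= 2,
            all(t_grid > 0 & t_grid < 1),
            t_reference %in% t_grid)
  architectures <- match.arg(architectures, cam_cnn_architectures(),
                             several.ok = TRUE)
  methods <- match.arg(methods, cam_methods(), several.ok = TRUE)
  structure(list(generator = generator, architectures = architectures,
                 methods = methods, t_grid = t_grid, train = train,
                 split_fractions = split_fractions,
                 augment_train = isTRUE(augment_train),
                 t_reference = t_reference, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full CAM-reliability pipeline
#'
#' Executes the six-step study design: generate the synthetic dataset,
#' split it leakage-free at the sample level, train one classifier per
#' architecture, compute CAM heatmaps for every damaged slice (class
#' `y = 1`) under every (model, method) combination, binarize over the
#' threshold grid, and score mean IoU against the ground-truth masks,
#' cross-method agreement (model fixed), cross-model agreement (method
#' fixed), the Spearman correlation of per-sample CAM damage with liquid
#' loss, and Kruskal-Wallis group tests of the agreement scores.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, result tables (CSV), a
#'   JSON summary and the run manifest are written there.
#' @param progress print stage progress.
#' @return list of class `camrel_run` with elements `manifest`, `accuracy`,
#'   `slice_metrics`, `phi`, `correlations`, `group_tests`, `per_sample`,
#'   and `models`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, progress = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (progress) message(...)

  say("[1/6] generating dataset")
  ds <- generate_dataset(cfg$generator)

  say("[2/6] splitting and preprocessing")
  split <- split_by_sample(ds, cfg$split_fractions, seed = cfg$seed + 1L)
  data <- dataset_tensors(ds, split, augment_train = cfg$augment_train,
                          seed = cfg$seed + 2L)

  say("[3/6] training classifiers")
  models <- list()
  accuracy <- NULL
  for (i in seq_along(cfg$architectures)) {
    arch <- cfg$architectures[i]
    m <- cam_cnn(arch, input_size = cfg$generator$image_size,
                 seed = cfg$seed + 100L + i)
    m <- cnn_train(m, data, cfg$train, seed = cfg$seed + 200L + i)
    models[[arch]] <- m
    accuracy <- rbind(accuracy, data.frame(
      model = arch,
      train = nn_accuracy(m, data$train$x, data$train$y),
      val = nn_accuracy(m, data$val$x, data$val$y),
      test = if (dim(data$test$x)[4] > 0)
        nn_accuracy(m, data$test$x, data$test$y) else NA_real_,
      epochs = nrow(m$trace)))
    say("    ", arch, ": val acc ", round(accuracy$val[i], 3))
  }

  say("[4/6] computing CAMs and binarized masks")
  say("[5/6] agreement statistics")
  slice_rows <- list(); phi_rows <- list(); frac_rows <- list()
  for (s in ds) {
    for (sl in seq_along(s$damaged_slices)) {
      img <- s$damaged_slices[[sl]]
      fg <- foreground_mask(img)
      truth <- s$truth_masks[[sl]]
      heat <- lapply(models, function(m) {
        h <- lapply(cfg$methods, function(me) compute_cam(me, m, img))
        names(h) <- cfg$methods
        h
      })
      slice_id <- paste0(s$sample_id, ":", sl)
      for (t in cfg$t_grid) {
        masks <- lapply(heat, function(hm)
          lapply(hm, binarize, t_cam = t, foreground = fg))
        for (arch in names(masks)) {
          for (me in cfg$methods) {
            slice_rows[[length(slice_rows) + 1L]] <- data.frame(
              sample_id = s$sample_id, slice = sl, model = arch,
              method = me, t_cam = t,
              iou_truth = iou(masks[[arch]][[me]], truth),
              cam_fraction = damage_fraction(masks[[arch]][[me]], fg))
          }
          if (length(cfg$methods) >= 2)
            phi_rows[[length(phi_rows) + 1L]] <-
              agreement_across_cams(masks[[arch]], model = arch,
                                    t_cam = t, slice = slice_id)
        }
        if (length(models) >= 2) {
          for (me in cfg$methods) {
            bym <- lapply(masks, `[[`, me)
            phi_rows[[length(phi_rows) + 1L]] <-
              agreement_across_models(bym, method = me, t_cam = t,
                                      slice = slice_id)
          }
        }
      }
    }
    say("    sample ", s$sample_id, " done")
  }
  slice_metrics <- do.call(rbind, slice_rows)
  phi <- do.call(rbind, phi_rows)

  say("[6/6] correlations and group tests")
  per_sample <- stats::aggregate(
    cam_fraction ~ sample_id + model + method,
    data = slice_metrics[slice_metrics$t_cam == cfg$t_reference, ], FUN = mean)
  ll <- setNames(vapply(ds, `[[`, numeric(1), "liquid_loss_pct"),
                 vapply(ds, `[[`, character(1), "sample_id"))
  per_sample$liquid_loss_pct <- ll[per_sample$sample_id]
  correlations <- NULL
  for (arch in names(models)) {
    for (me in cfg$methods) {
      d <- per_sample[per_sample$model == arch & per_sample$method == me, ]
      cr <- suppressWarnings(
        correlate_with_liquid_loss(d$cam_fraction, d$liquid_loss_pct))
      correlations <- rbind(correlations, data.frame(
        model = arch, method = me, rho = cr$rho, p_value = cr$p_value,
        n = cr$n))
    }
  }
  group_tests <- NULL
  pr <- phi[phi$t_cam == cfg$t_reference, ]
  if (nrow(pr)) {
    for (ax in c("model", "method")) {
      d <- pr[pr$axis_type == ax, ]
      if (length(unique(d$axis)) >= 2) {
        g <- split(d$value, d$axis)
        kt <- compare_groups(g)
        group_tests <- rbind(group_tests, data.frame(
          axis = ax, H = kt$H, df = kt$df, p_value = kt$p_value))
      }
    }
  }

  manifest <- list(
    seed = cfg$seed,
    architectures = cfg$architectures,
    methods = cfg$methods,
    t_grid = cfg$t_grid,
    t_reference = cfg$t_reference,
    n_samples = length(ds),
    slices_per_sample = cfg$generator$slices_per_sample,
    image_size = cfg$generator$image_size,
    n_method_pairs = if (length(cfg$methods) >= 2)
      choose(length(cfg$methods), 2) else 0L,
    n_model_pairs = if (length(cfg$architectures) >= 2)
      choose(length(cfg$architectures), 2) else 0L,
    split = table(split$partition))

  res <- structure(list(manifest = manifest, accuracy = accuracy,
                        slice_metrics = slice_metrics, phi = phi,
                        correlations = correlations,
                        group_tests = group_tests,
                        per_sample = per_sample, models = models,
                        split = split),
                   class = "camrel_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.camrel_run <- function(x, ...) {
  m <- x$manifest
  cat("<camrel_run>", m$n_samples, "samples,",
      length(m$architectures), "models x", length(m$methods), "CAM methods\n")
  cat("  validation accuracy:",
      paste(sprintf("%s %.2f", x$accuracy$model, x$accuracy$val),
            collapse = ", "), "\n")
  pm <- x$phi[x$phi$t_cam == 0.5 & x$phi$axis_type == "model", "value"]
  pc <- x$phi[x$phi$t_cam == 0.5 & x$phi$axis_type == "method", "value"]
  if (length(pm)) cat(sprintf("  median phi (across CAM methods, t=0.5): %.3f\n",
                              median(pm)))
  if (length(pc)) cat(sprintf("  median phi (across CNN models, t=0.5): %.3f\n",
                              median(pc)))
  invisible(x)
}

write_run <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$accuracy, file.path(dir, "accuracy.csv"), row.names = FALSE)
  write.csv(res$slice_metrics, file.path(dir, "slice_metrics.csv"),
            row.names = FALSE)
  write.csv(res$phi, file.path(dir, "agreement.csv"), row.names = FALSE)
  write.csv(res$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  if (!is.null(res$group_tests))
    write.csv(res$group_tests, file.path(dir, "group_tests.csv"),
              row.names = FALSE)
  write.csv(res$per_sample, file.path(dir, "per_sample.csv"),
            row.names = FALSE)
  summary <- run_summary(res, t_ref = res$manifest$t_reference)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(res$manifest, unclass),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summary statistics of a pipeline run
#'
#' Medians and interquartile ranges of the agreement distributions at the
#' reference threshold, mean accuracies, the best liquid-loss correlation
#' and the group tests, in a plain list ready for JSON export.
#'
#' @param res a [run_pipeline()] result.
#' @param t_ref threshold at which distributions are summarised.
#' @return named list.
#' @export
run_summary <- function(res, t_ref = 0.5) {
  qs <- function(v) if (length(v))
    list(median = median(v), q1 = unname(quantile(v, 0.25)),
         q3 = unname(quantile(v, 0.75))) else NULL
  pm <- res$phi[res$phi$t_cam == t_ref & res$phi$axis_type == "model", "value"]
  pc <- res$phi[res$phi$t_cam == t_ref & res$phi$axis_type == "method", "value"]
  sm <- res$slice_metrics[res$slice_metrics$t_cam == t_ref, ]
  best <- res$correlations[which.max(res$correlations$rho), , drop = FALSE]
  list(accuracy = list(train = mean(res$accuracy$train),
                       val = mean(res$accuracy$val),
                       test = mean(res$accuracy$test)),
       miou_truth = qs(sm$iou_truth),
       phi_across_methods = qs(pm),
       phi_across_models = qs(pc),
       best_liquid_loss_correlation = if (nrow(best))
         list(model = best$model, method = best$method, rho = best$rho,
              p_value = best$p_value) else NULL,
       group_tests = res$group_tests)
}
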