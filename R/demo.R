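#' Desk-scale study conditions
#'
#' The package's canonical small-scale experiment: 20 synthetic scenes
#' (112 x 112 px, 8 nuclei of mean radius 6-9 px, 40 percent of nuclei
#' overlapping a neighbour, mild noise), a depth-2 / 8-filter / 16-ray
#' network trained for 150 epochs with SGD (learning rate 0.05,
#' momentum 0.9), followed by threshold optimization on the training
#' patches. The overlap-containing scenes are the regime the
#' star-convex detector exists for, and where the marker-controlled
#' watershed baseline loses nuclei. The first 16 scenes are the
#' training pool (with an internal 80:20 train-validation split) and
#' the last 4 are held out for object-level evaluation. These sizes run
#' end to end in a few minutes on one CPU.
#'
#' @param seed Base integer seed; scene i uses `seed * 1000 + i`.
#' @param n_scenes Number of scenes (default 20).
#' @return `demo_scenes()`: list of `sish_scene`.
#' @export
demo_scenes <- function(seed = 1L, n_scenes = 20) {
  lapply(seq_len(n_scenes), function(i)
    generate_scene(scene_config(height = 112, width = 112, n_nuclei = 8,
                                radius_range = c(6, 9),
                                overlap_fraction = 0.4, border_fraction = 0,
                                noise_sd = 2,
                                seed = as.integer(seed) * 1000L + i)))
}

#' @rdname demo_scenes
#' @param epochs Training epochs (default 150).
#' @param augment Geometric augmentation flag.
#' @return `demo_train_config()`: a [train_config()].
#' @export
demo_train_config <- function(seed = 1L, epochs = 150, augment = TRUE) {
  train_config(learning_rate = 0.05, momentum = 0.9, batch_size = 4,
               epochs = epochs, patch_size = 112, val_fraction = 0.2,
               dist_loss_weight = 0.2, seed = as.integer(seed),
               depth = 2, base_filters = 8, n_rays = 16, augment = augment)
}

#' Train the demo model on a scene set
#'
#' Trains on the first `n - n_test` scenes of `scenes` using the
#' demo configuration, optimizes detection thresholds on the training
#' patches, and returns the fitted predictor together with the
#' held-out scene indices.
#'
#' @param scenes Scene list from [demo_scenes()].
#' @param seed Training seed.
#' @param n_test Number of trailing scenes held out (default 4).
#' @param epochs Training epochs.
#' @return List with `predictor`, `record`, `test_idx`.
#' @export
demo_fit <- function(scenes, seed = 1L, n_test = 4, epochs = 150) {
  n <- length(scenes)
  train_scenes <- scenes[seq_len(n - n_test)]
  patches <- lapply(train_scenes, function(s)
    list(image = s$image, mask = s$mask))
  fit <- train_predictor(patches, demo_train_config(seed, epochs))
  predictor <- optimize_thresholds(fit$predictor, patches,
                                   iou_grid = c(0.3, 0.4))
  list(predictor = predictor, record = fit$record,
       test_idx = seq(n - n_test + 1, n))
}

#' Evaluate a detector over scenes, pooling counts
#'
#' @param detect Function `image -> detection mask` (an H x W integer
#'   matrix or a `detection_set`).
#' @param scenes Scenes to evaluate on.
#' @param iou_thresh Match threshold.
#' @return List with pooled `tp`, `fp`, `fn`, `f1` (fraction in
#'   \[0, 1\]).
#' @export
pooled_detection_f1 <- function(detect, scenes, iou_thresh = 0.5) {
  tp <- fp <- fn <- 0L
  for (scene in scenes) {
    out <- detect(scene$image)
    if (inherits(out, "detection_set")) out <- out$instance_mask
    m <- match_instances(out, scene$mask, iou_thresh)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  list(tp = tp, fp = fp, fn = fn,
       f1 = if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}
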