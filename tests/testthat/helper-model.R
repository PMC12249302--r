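# Shared trained models, built once per test session. Training is the
# expensive step, so the demo fit and the single-patch overfit are
# cached and reused by the model, pipeline, and acceptance tests.

.fit_cache <- new.env(parent = emptyenv())

cached_demo <- function() {
  if (is.null(.fit_cache$demo)) {
    scenes <- demo_scenes(seed = 2L)
    fit <- demo_fit(scenes, seed = 11L)
    .fit_cache$demo <- list(scenes = scenes, predictor = fit$predictor,
                            record = fit$record, test_idx = fit$test_idx)
  }
  .fit_cache$demo
}

cached_overfit <- function() {
  if (is.null(.fit_cache$overfit)) {
    scene <- generate_scene(scene_config(height = 112, width = 112,
                                         n_nuclei = 8, radius_range = c(6, 9),
                                         overlap_fraction = 0,
                                         border_fraction = 0, noise_sd = 2,
                                         seed = 777L))
    patch <- list(image = scene$image, mask = scene$mask)
    fit <- train_predictor(rep(list(patch), 5),
                           demo_train_config(seed = 3L, epochs = 150,
                                             augment = FALSE))
    predictor <- optimize_thresholds(fit$predictor, list(patch),
                                     iou_grid = c(0.2, 0.3, 0.4))
    .fit_cache$overfit <- list(scene = scene, predictor = predictor,
                               record = fit$record)
  }
  .fit_cache$overfit
}
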