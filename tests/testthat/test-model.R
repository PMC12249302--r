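test_that("the predictor obeys its output contracts", {
  cfg <- train_config(patch_size = 64, depth = 2, base_filters = 4,
                      n_rays = 8, seed = 5, epochs = 1)
  pred <- build_predictor(cfg)
  withr::with_seed(1, img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)))
  maps <- predict_maps(pred, img)
  expect_identical(dim(maps$prob), c(64L, 64L))
  expect_identical(dim(maps$dist), c(64L, 64L, 8L))
  expect_true(all(maps$prob >= 0 & maps$prob <= 1))
  expect_true(all(maps$dist >= 0))
  # other input sizes compatible with the depth also work
  img2 <- array(runif(128 * 64 * 3), c(128, 64, 3))
  maps2 <- predict_maps(pred, img2)
  expect_identical(dim(maps2$prob), c(128L, 64L))
  # incompatible patch size is rejected at configuration time
  expect_error(train_config(patch_size = 100, depth = 3), "patch_size")
})

test_that("seeded builds are identical; different seeds differ", {
  cfg <- train_config(patch_size = 32, depth = 1, base_filters = 4,
                      n_rays = 8, seed = 9)
  p1 <- build_predictor(cfg); p2 <- build_predictor(cfg)
  expect_identical(p1$params, p2$params)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(build_predictor(cfg2)$params, p1$params))
})

test_that("the composite loss matches a hand-computed toy example", {
  # 3 x 3 patch, 8 rays: computed with plain arithmetic below
  prob_t <- matrix(c(0, 0.5, 1, 0, 0, 0, 0, 0.25, 0), 3)
  dist_t <- array(2, c(3, 3, 8)); dist_t[prob_t == 0] <- 0
  pred <- list(prob = matrix(0.5, 3, 3), dist = array(3, c(3, 3, 8)))
  got <- detection_loss(pred, list(prob = prob_t, dist = dist_t), lambda = 0.5)
  bce_manual <- mean(-(prob_t * log(0.5) + (1 - prob_t) * log(0.5)))
  # distance: |3-2| = 1 on every ray at weighted pixels
  dist_manual <- sum(prob_t * 1) / sum(prob_t)
  expect_equal(got$bce, bce_manual)
  expect_equal(got$dist_loss, dist_manual)
  expect_equal(got$loss, bce_manual + 0.5 * dist_manual)
  # exact distance prediction zeroes the distance term
  pred2 <- list(prob = matrix(0.5, 3, 3), dist = dist_t)
  expect_equal(detection_loss(pred2, list(prob = prob_t, dist = dist_t),
                              0.5)$dist_loss, 0)
  # all-background target: distance term is 0 whatever the predictions
  zero_t <- list(prob = matrix(0, 3, 3), dist = array(0, c(3, 3, 8)))
  expect_equal(detection_loss(pred, zero_t, 0.5)$dist_loss, 0)
})

test_that("the C++ training loss agrees with the R reference on random tensors", {
  cfg <- train_config(patch_size = 16, depth = 1, base_filters = 4,
                      n_rays = 8, seed = 2)
  pred <- build_predictor(cfg)
  withr::with_seed(3, {
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    tp <- matrix(runif(256), 16); tp[tp < 0.5] <- 0
    td <- array(runif(256 * 8, 0, 6), c(16, 16, 8)); td[array(tp == 0, dim(td))] <- 0
  })
  run <- sishdetect:::.unet_run(pred$params, 1L, 4L, 8L, 3L, img,
                                as.numeric(tp), as.numeric(td), 0.2,
                                FALSE, FALSE)
  ref <- detection_loss(list(prob = run$prob, dist = run$dist),
                        list(prob = tp, dist = td), 0.2)
  expect_equal(run$loss, ref$loss, tolerance = 1e-10)
  expect_equal(run$bce, ref$bce, tolerance = 1e-10)
})

test_that("short training descends and is reproducible", {
  scenes <- lapply(1:6, function(i) generate_scene(scene_config(
    height = 64, width = 64, n_nuclei = 3, radius_range = c(5, 7),
    overlap_fraction = 0, border_fraction = 0, noise_sd = 2,
    seed = 400 + i)))
  patches <- lapply(scenes, function(s) list(image = s$image, mask = s$mask))
  cfg <- train_config(learning_rate = 0.05, epochs = 6, patch_size = 64,
                      depth = 2, base_filters = 6, n_rays = 8, seed = 13)
  fit1 <- train_predictor(patches, cfg)
  expect_lt(tail(fit1$record$val_loss, 1), fit1$record$val_loss[1])
  expect_identical(nrow(fit1$record), 6L)
  expect_identical(attr(fit1$record, "best_epoch"),
                   which.min(fit1$record$val_loss))
  fit2 <- train_predictor(patches, cfg)
  expect_identical(fit1$record$train_loss, fit2$record$train_loss)
  expect_identical(fit1$predictor$params, fit2$predictor$params)
  expect_error(train_predictor(patches[1:3], cfg), "at least 5")
})

test_that("checkpoints round-trip through disk", {
  cfg <- train_config(patch_size = 32, depth = 1, base_filters = 4,
                      n_rays = 8, seed = 1)
  pred <- build_predictor(cfg)
  path <- tempfile(fileext = ".rds")
  save_predictor(pred, path, record = data.frame(epoch = 1, val = 0.5))
  back <- load_predictor(path)
  expect_identical(back$params, pred$params)
  expect_identical(attr(back, "record")$val, 0.5)
  expect_error(load_predictor(tempfile()), "checkpoint")
})
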