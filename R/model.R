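#' Training configuration for the star-convex predictor
#'
#' Defaults mirror the full-scale training recipe (SGD, learning rate
#' 1e-4, momentum 0.9, batch size 4, 256 px patches, 100 epochs, 80:20
#' train-validation split); tests and the bundled demo pipeline use a
#' much smaller network and patch size, larger learning rate, and fewer
#' epochs, which is what desk-scale CPU training requires.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Patches per gradient step.
#' @param epochs Training epochs.
#' @param patch_size Square patch side (must be a multiple of
#'   `2^depth`).
#' @param val_fraction Validation fraction in (0, 1).
#' @param dist_loss_weight Weight of the distance (MAE) loss term
#'   relative to the probability BCE term.
#' @param seed Integer seed for init, shuffling, and augmentation.
#' @param lr_decay Multiplier applied to the learning rate over the last
#'   30 percent of the epochs (1 = constant rate).
#' @param depth U-Net depth (number of pooling stages).
#' @param base_filters Filters at the first level (doubled per stage).
#' @param n_rays Radial directions predicted per pixel.
#' @param augment Apply random 90-degree rotations and flips.
#' @param prob_target `"soft"` trains the probability head towards the
#'   center-weighted object probability (center pixels score highest,
#'   which polygon selection relies on); `"binary"` uses the 0/1
#'   foreground indicator.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         batch_size = 4, epochs = 100, patch_size = 256,
                         val_fraction = 0.2, dist_loss_weight = 0.2,
                         seed = 1L, depth = 3, base_filters = 32,
                         n_rays = 32, augment = TRUE, lr_decay = 0.2,
                         prob_target = c("soft", "binary")) {
  cfg <- list(learning_rate = learning_rate, momentum = momentum,
              lr_decay = lr_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              patch_size = as.integer(patch_size),
              val_fraction = val_fraction,
              dist_loss_weight = dist_loss_weight, seed = as.integer(seed),
              depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              n_rays = as.integer(n_rays), augment = isTRUE(augment),
              prob_target = match.arg(prob_target))
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must lie strictly between 0 and 1")
  if (cfg$patch_size %% 2^cfg$depth != 0)
    stop("patch_size must be a multiple of 2^depth")
  if (cfg$augment && cfg$n_rays %% 4 != 0)
    stop("augmentation requires n_rays divisible by 4")
  class(cfg) <- "train_config"
  cfg
}

#' Build an untrained star-convex predictor
#'
#' Constructs the compact U-Net (contracting path for context, expansive
#' path for localization, skip connections) with a sigmoid object
#' probability head and a softplus radial distance head, and initializes
#' its weights (He initialization, seeded).
#'
#' @param config A [train_config()].
#' @return An object of class `sc_predictor` holding the flat parameter
#'   vector and architecture description.
#' @export
build_predictor <- function(config) {
  spec <- .unet_layer_spec(config$depth, config$base_filters,
                           config$n_rays, 3L)
  sizes <- spec[, 3]^2 * spec[, 1] * spec[, 2]
  n_layers <- nrow(spec)
  params <- withr::with_seed(config$seed, {
    unlist(lapply(seq_len(n_layers), function(i) {
      fan_in <- spec[i, 3]^2 * spec[i, 1]
      # head biases start at the background prior (probability head) and
      # at a typical in-object radius (softplus^-1(3), distance head)
      bias <- if (i == n_layers - 1) -2 else if (i == n_layers) 1.8 else 0
      c(rnorm(sizes[i], 0, sqrt(2 / fan_in)), rep(bias, spec[i, 2]))
    }))
  })
  structure(list(params = params, depth = config$depth,
                 base_filters = config$base_filters,
                 n_rays = config$n_rays, in_channels = 3L,
                 config = config),
            class = "sc_predictor")
}

#' Percentile intensity normalization
#'
#' Scales image intensities to \[0, 1\] between the 1st and 99th
#' percentiles (computed jointly over channels), clipping outside.
#'
#' @param image Numeric array.
#' @param lower,upper Percentiles in 0-100.
#' @return Array of the same shape with values in \[0, 1\].
#' @export
percentile_normalize <- function(image, lower = 1, upper = 99) {
  q <- quantile(image, c(lower, upper) / 100, names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim(image)))
  pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Run the predictor on a single patch
#'
#' @param predictor An `sc_predictor`.
#' @param image H x W x 3 array; intensities are percentile-normalized
#'   internally unless `normalize = FALSE`. H and W must be multiples
#'   of `2^depth`.
#' @param normalize Apply [percentile_normalize()] first.
#' @return List with `prob` (H x W in \[0, 1\]) and `dist`
#'   (H x W x n_rays, >= 0).
#' @export
predict_maps <- function(predictor, image, normalize = TRUE) {
  x <- if (normalize) percentile_normalize(image) else image
  x <- array(as.numeric(x), dim(image))
  .unet_run(predictor$params, predictor$depth, predictor$base_filters,
            predictor$n_rays, predictor$in_channels, x,
            numeric(0), numeric(0), 0, FALSE, FALSE)
}

#' Composite detection loss
#'
#' `L = BCE(prob) + lambda * weighted-MAE(dist)`, where the distance
#' term averages `|pred - target|` over rays, weights each pixel by the
#' target object probability, and normalizes by the total weight, so
#' background pixels (zero probability) contribute nothing to it; an
#' all-background target has distance term 0 by definition.
#'
#' @param pred List with `prob` and `dist` (as from [predict_maps()]).
#' @param target List with `prob` (H x W) and `dist` (H x W x n_rays),
#'   e.g. from [radial_ground_truth()].
#' @param lambda Distance term weight.
#' @param prob_target `"soft"` or `"binary"` probability target.
#' @return List with `loss`, `bce`, `dist_loss`.
#' @export
detection_loss <- function(pred, target, lambda = 0.2,
                           prob_target = "soft") {
  stopifnot(all(dim(pred$prob) == dim(target$prob)),
            all(dim(pred$dist) == dim(target$dist)))
  p <- pmin(pmax(as.numeric(pred$prob), 1e-12), 1 - 1e-12)
  y <- as.numeric(target$prob)
  if (prob_target == "binary") y <- as.numeric(y > 0)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  w <- as.numeric(target$prob)
  wsum <- sum(w)
  if (wsum > 0) {
    n_rays <- dim(target$dist)[3]
    ae <- abs(matrix(pred$dist, ncol = n_rays) -
              matrix(target$dist, ncol = n_rays))
    dl <- sum(w * rowMeans(ae)) / wsum
  } else dl <- 0
  list(loss = bce + lambda * dl, bce = bce, dist_loss = dl)
}

#' Radial ground truth (probability + distances) from an instance mask
#'
#' @param mask H x W integer instance mask.
#' @param n_rays Number of rays.
#' @return List with `prob` and `dist`.
#' @export
radial_ground_truth <- function(mask, n_rays = 32) {
  list(prob = compute_object_probability(mask),
       dist = compute_radial_distances(mask, n_rays))
}

#' Train the star-convex predictor
#'
#' SGD with momentum on the composite loss over (image, instance mask)
#' patches. An 80:20 (by default) train-validation split is applied;
#' optional augmentation draws a seeded 90-degree rotation and flips per
#' patch per epoch, recomputing the radial targets from the transformed
#' mask. The returned predictor carries the parameters of the epoch
#' with the lowest validation loss.
#'
#' @param patches List of lists with elements `image` (H x W x 3) and
#'   `mask` (H x W integer); all patches must share the same size,
#'   a multiple of `2^depth`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `predictor` (an `sc_predictor`) and `record` (a
#'   data frame of per-epoch train/validation losses and components,
#'   with attribute `best_epoch`).
#' @export
train_predictor <- function(patches, config, verbose = FALSE) {
  if (length(patches) < 5) stop("need at least 5 patches to train")
  withr::with_seed(config$seed + 1L, train_predictor_impl(patches, config, verbose))
}

train_predictor_impl <- function(patches, config, verbose) {
  n <- length(patches)
  n_val <- max(1, round(config$val_fraction * n))
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]

  prep <- function(p, aug_seed = NULL) {
    img <- p$image; msk <- p$mask
    if (!is.null(aug_seed)) {
      a <- augment_patch(list(image = img, mask = msk), aug_seed)
      img <- a$image; msk <- a$mask
    }
    gt <- radial_ground_truth(msk, config$n_rays)
    list(image = array(as.numeric(percentile_normalize(img)), dim(img)),
         prob = as.numeric(gt$prob), dist = as.numeric(gt$dist))
  }
  val_data <- lapply(patches[val_idx], prep)

  predictor <- build_predictor(config)
  params <- predictor$params
  velocity <- numeric(length(params))
  binary <- config$prob_target == "binary"
  lambda <- config$dist_loss_weight

  run1 <- function(par, d, grad) {
    .unet_run(par, config$depth, config$base_filters, config$n_rays, 3L,
              d$image, d$prob, d$dist, lambda, binary, grad)
  }
  eval_set <- function(par, data) {
    comp <- vapply(data, function(d) {
      r <- run1(par, d, FALSE)
      c(r$loss, r$bce, r$dist_loss)
    }, numeric(3))
    rowMeans(comp)
  }

  rec <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), train_bce = numeric(0),
                    train_dist = numeric(0), val_bce = numeric(0),
                    val_dist = numeric(0), accuracy = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  lr_decay <- config$lr_decay %||% 1
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      if (epoch > 0.7 * config$epochs) lr_decay else 1
    order_idx <- sample(train_idx)
    aug_seeds <- sample.int(.Machine$integer.max - 1L, length(order_idx))
    ep_comp <- numeric(3); nb <- 0
    for (b in seq(1, length(order_idx), by = config$batch_size)) {
      bidx <- order_idx[b:min(b + config$batch_size - 1, length(order_idx))]
      grad <- numeric(length(params)); comp <- numeric(3)
      for (j in seq_along(bidx)) {
        d <- prep(patches[[bidx[j]]],
                  if (config$augment) aug_seeds[which(order_idx == bidx[j])[1]])
        r <- run1(params, d, TRUE)
        if (!is.finite(r$loss))
          stop(sprintf("non-finite loss at epoch %d (bce=%.4g dist=%.4g)",
                       epoch, r$bce, r$dist_loss))
        grad <- grad + r$grad
        comp <- comp + c(r$loss, r$bce, r$dist_loss)
      }
      grad <- grad / length(bidx)
      velocity <- config$momentum * velocity - lr * grad
      params <- params + velocity
      ep_comp <- ep_comp + comp / length(bidx); nb <- nb + 1
    }
    ep_comp <- ep_comp / nb
    val <- eval_set(params, val_data)
    acc <- prob_accuracy(params, config, val_data)
    rec <- rbind(rec, data.frame(epoch = epoch, train_loss = ep_comp[1],
                                 val_loss = val[1], train_bce = ep_comp[2],
                                 train_dist = ep_comp[3], val_bce = val[2],
                                 val_dist = val[3], accuracy = acc))
    if (val[1] < best$loss)
      best <- list(loss = val[1], params = params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_comp[1], val[1], acc))
  }
  predictor$params <- best$params
  attr(rec, "best_epoch") <- best$epoch
  attr(rec, "val_idx") <- val_idx
  list(predictor = predictor, record = rec, val_idx = val_idx)
}

# Pixel accuracy of the thresholded probability map on a data list.
prob_accuracy <- function(params, config, data) {
  mean(vapply(data, function(d) {
    r <- .unet_run(params, config$depth, config$base_filters,
                   config$n_rays, 3L, d$image, numeric(0), numeric(0),
                   0, FALSE, FALSE)
    mean((as.numeric(r$prob) > 0.5) == (d$prob > 0))
  }, numeric(1)))
}

#' Optimize detection thresholds on labelled patches
#'
#' Sweeps the candidate probability threshold (and optionally the NMS
#' IoU threshold) over a grid, scoring object-level F1 of the full
#' inference chain against the reference masks, and stores the best
#' combination in the predictor (used as defaults by
#' [predict_image()]). Ties prefer the lowest probability threshold.
#'
#' @param predictor An `sc_predictor`.
#' @param patches List of lists with `image` and `mask`.
#' @param prob_grid Probability thresholds to try.
#' @param iou_grid NMS IoU thresholds to try.
#' @param match_iou Match threshold for scoring (default 0.5).
#' @return The predictor with a `thresholds` element
#'   (`prob_thresh`, `iou_thresh`, `f1`).
#' @export
optimize_thresholds <- function(predictor, patches,
                                prob_grid = seq(0.3, 0.85, by = 0.05),
                                iou_grid = 0.4, match_iou = 0.5) {
  maps <- lapply(patches, function(p) predict_maps(predictor, p$image))
  best <- list(f1 = -1, prob_thresh = prob_grid[1], iou_thresh = iou_grid[1])
  for (it in iou_grid) for (pt in prob_grid) {
    tp <- fp <- fn <- 0
    for (j in seq_along(patches)) {
      cands <- candidate_polygons(maps[[j]]$prob, maps[[j]]$dist, pt)
      det <- rasterize_detections(greedy_nms(cands, it),
                                  dim(patches[[j]]$mask))
      m <- match_instances(det$instance_mask, patches[[j]]$mask, match_iou)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    f1 <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    if (f1 > best$f1 + 1e-12)
      best <- list(f1 = f1, prob_thresh = pt, iou_thresh = it)
  }
  predictor$thresholds <- best
  predictor
}

#' Save / load a predictor checkpoint
#'
#' The checkpoint stores the architecture description, the flat
#' parameter vector, and (optionally) the training record.
#'
#' @param predictor An `sc_predictor`.
#' @param path File path.
#' @param record Optional training record to store alongside.
#' @return `load_predictor` returns the predictor (with the record, if
#'   any, attached as attribute `record`).
#' @export
save_predictor <- function(predictor, path, record = NULL) {
  obj <- unclass(predictor)
  obj$record <- record
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("corrupt or unreadable checkpoint: ", conditionMessage(e)))
  rec <- obj$record
  obj$record <- NULL
  pred <- structure(obj, class = "sc_predictor")
  attr(pred, "record") <- rec
  pred
}
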