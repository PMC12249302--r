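#' Read / write RGB images and instance masks
#'
#' Thin wrappers around EBImage I/O converting between the package's
#' (row, col) array convention and EBImage's (x, y) layout. RGB images
#' are 8-bit PNG; instance masks are 16-bit single-channel TIFF.
#'
#' @param path File path.
#' @param image H x W x 3 integer array (0-255).
#' @param mask H x W integer matrix.
#' @return Readers return the array/matrix; writers return `path`
#'   invisibly.
#' @export
read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), c(dim(d), 3))
  arr <- aperm(d[, , 1:3, drop = FALSE], c(2, 1, 3))
  out <- array(as.integer(round(arr * 255)), dim(arr))
  out
}

#' @rdname read_rgb
#' @export
write_rgb <- function(image, path) {
  EBImage::writeImage(EBImage::Image(aperm(image, c(2, 1, 3)) / 255,
                                     colormode = "Color"), path)
  invisible(path)
}

#' @rdname read_rgb
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- d[, , 1]
  matrix(as.integer(round(t(d) * 65535)), ncol(d), nrow(d))
}

#' @rdname read_rgb
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("mask labels exceed 16-bit range")
  EBImage::writeImage(EBImage::Image(t(mask) / 65535), path,
                      type = "tiff", bits.per.sample = 16)
  invisible(path)
}

#' Full star-convex inference on an image of any size
#'
#' Percentile-normalizes the image, runs the predictor (tiling large
#' images with overlapping 256 px tiles and merging candidates by a
#' single global NMS), thresholds candidate pixels, applies greedy NMS
#' and rasterizes the kept polygons.
#'
#' @param image H x W x 3 RGB array, at least 64 x 64.
#' @param predictor An `sc_predictor` (or checkpoint path).
#' @param prob_thresh Candidate probability threshold; defaults to the
#'   predictor's [optimize_thresholds()] value if present, else 0.5.
#' @param iou_thresh NMS IoU threshold; same defaulting, else 0.4.
#' @param tile Tile side for large images (default 256).
#' @param overlap Tile overlap in pixels (default 64).
#' @param min_area Post-processing: detected instances smaller than this
#'   many pixels are removed (default 30, the package-wide
#'   small-region threshold; 0 disables).
#' @return A `detection_set`.
#' @export
predict_image <- function(image, predictor, prob_thresh = NULL,
                          iou_thresh = NULL, tile = 256, overlap = 64,
                          min_area = 30) {
  if (is.character(predictor)) predictor <- load_predictor(predictor)
  if (is.null(prob_thresh))
    prob_thresh <- predictor$thresholds$prob_thresh %||% 0.5
  if (is.null(iou_thresh))
    iou_thresh <- predictor$thresholds$iou_thresh %||% 0.4
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < 64 || W < 64) stop("image must be at least 64 x 64")
  norm <- array(as.numeric(percentile_normalize(image)), dim(image))
  mult <- 2^predictor$depth
  centers <- matrix(numeric(0), 0, 2)
  radii <- matrix(numeric(0), 0, predictor$n_rays)
  scores <- numeric(0)
  step <- tile - overlap
  r_starts <- tile_starts(H, tile, step)
  c_starts <- tile_starts(W, tile, step)
  for (r0 in r_starts) for (c0 in c_starts) {
    r1 <- min(H, r0 + tile - 1); c1 <- min(W, c0 + tile - 1)
    sub <- norm[r0:r1, c0:c1, , drop = FALSE]
    hh <- dim(sub)[1]; ww <- dim(sub)[2]
    hp <- ceiling(hh / mult) * mult; wp <- ceiling(ww / mult) * mult
    if (hp != hh || wp != ww)
      sub <- sub[reflect_index(hh, hp), reflect_index(ww, wp), , drop = FALSE]
    maps <- predict_maps(predictor, sub, normalize = FALSE)
    prob <- maps$prob[seq_len(hh), seq_len(ww)]
    dist <- maps$dist[seq_len(hh), seq_len(ww), , drop = FALSE]
    # core region: exclude half the overlap except at image edges
    m <- overlap %/% 2
    keep_r <- c(if (r0 > 1) r0 + m else 1, if (r1 < H) r1 - m else H)
    keep_c <- c(if (c0 > 1) c0 + m else 1, if (c1 < W) c1 - m else W)
    cands <- candidate_polygons(prob, dist, prob_thresh)
    if (length(cands$scores) == 0) next
    gr <- cands$centers[, 1] + r0 - 1
    gc <- cands$centers[, 2] + c0 - 1
    sel <- gr >= keep_r[1] & gr <= keep_r[2] & gc >= keep_c[1] & gc <= keep_c[2]
    if (!any(sel)) next
    centers <- rbind(centers, cbind(gr[sel], gc[sel]))
    radii <- rbind(radii, cands$radii[sel, , drop = FALSE])
    scores <- c(scores, cands$scores[sel])
  }
  kept <- greedy_nms(list(centers = centers, radii = radii, scores = scores),
                     iou_thresh)
  det <- rasterize_detections(kept, c(H, W))
  if (min_area > 0) det <- filter_detections(det, min_area)
  det
}

# Drop detected instances below min_area pixels and renumber.
filter_detections <- function(det, min_area) {
  n <- nrow(det$centroids)
  if (n == 0) return(det)
  areas <- tabulate(det$instance_mask[det$instance_mask > 0], nbins = n)
  keep <- which(areas >= min_area)
  if (length(keep) == n) return(det)
  mask <- det$instance_mask
  relabel <- integer(n); relabel[keep] <- seq_along(keep)
  drop_sel <- mask > 0 & !(mask %in% keep)
  mask[drop_sel] <- 0L
  mask[mask > 0] <- relabel[mask[mask > 0]]
  structure(list(polygons = list(centers = det$polygons$centers[keep, , drop = FALSE],
                                 radii = det$polygons$radii[keep, , drop = FALSE],
                                 scores = det$polygons$scores[keep]),
                 centroids = det$centroids[keep, , drop = FALSE],
                 instance_mask = mask),
            class = "detection_set")
}

tile_starts <- function(n, tile, step) {
  if (n <= tile) return(1L)
  s <- seq(1L, n - tile, by = step)
  if (s[length(s)] + tile - 1 < n) s <- c(s, n - tile + 1L)
  as.integer(s)
}

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. The demo defaults (20
#' small synthetic scenes, a depth-2 / 8-filter network, 16 rays, 15
#' epochs) run end to end on one CPU in minutes.
#'
#' @param seed Global pipeline seed.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    synth = list(n_scenes = 20, height = 96, width = 96, n_nuclei = 6,
                 radius_range = c(5, 8), overlap_fraction = 0,
                 border_fraction = 0, noise_sd = 2),
    split = list(test_fraction = 0.2),
    foreground = list(local_block = 51, min_hole = 20, open_radius = 2),
    pseudolabel = list(min_area = 30, marker_sep = 7),
    patchify = list(patch_size = 96, stride = 96, min_foreground = 0.02),
    train = list(learning_rate = 0.05, momentum = 0.9, batch_size = 4,
                 epochs = 15, val_fraction = 0.2, dist_loss_weight = 0.2,
                 depth = 2, base_filters = 8, n_rays = 16, augment = TRUE),
    predict = list(prob_thresh = 0.5, iou_thresh = 0.4, tile = 256,
                   overlap = 64),
    evaluate = list(iou_thresh = 0.5)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  defaults <- unclass(pipeline_config())
  check <- function(x, def, path) {
    unknown <- setdiff(names(x), names(def))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    for (nm in names(x))
      if (is.list(def[[nm]])) check(x[[nm]], def[[nm]], paste0(path, nm, "$"))
  }
  check(unclass(cfg), defaults, "")
  merged <- utils::modifyList(defaults, unclass(cfg))
  if (merged$train$val_fraction <= 0 || merged$train$val_fraction >= 1)
    stop("train$val_fraction must lie strictly between 0 and 1")
  if (merged$split$test_fraction <= 0 || merged$split$test_fraction >= 1)
    stop("split$test_fraction must lie strictly between 0 and 1")
  class(merged) <- "pipeline_config"
  merged
}

#' Run the full detection pipeline
#'
#' Executes all stages in order — scene synthesis, stain normalization,
#' foreground extraction, watershed pseudo-labeling, patch curation,
#' model training, prediction on held-out scenes, and object-level
#' evaluation against the generator's ground truth — persisting every
#' intermediate artifact plus a manifest with content hashes. Re-running
#' with the same configuration reproduces identical artifacts.
#'
#' @param config A [pipeline_config()] (possibly partial; validated and
#'   completed with defaults). Unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return The run directory, invisibly; its `manifest.json` lists each
#'   stage with inputs, outputs, seed and a parameter hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), stages = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  say <- function(...) if (verbose) message(sprintf(...))
  finish_stage <- function(name, outputs, seed = NULL, params = NULL) {
    manifest$stages[[name]] <<- list(
      stage = name, outputs = file_hashes(outputs),
      seed = seed, parameter_hash = config_hash(params))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  on_stage_error <- function(name) function(e) {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  }

  # 1. synth
  say("stage synth: generating %d scenes", cfg$synth$n_scenes)
  scenes_dir <- file.path(out_dir, "scenes")
  dir.create(scenes_dir, showWarnings = FALSE)
  scenes <- tryCatch({
    lapply(seq_len(cfg$synth$n_scenes), function(i) {
      sc <- generate_scene(scene_config(
        height = cfg$synth$height, width = cfg$synth$width,
        n_nuclei = cfg$synth$n_nuclei,
        radius_range = cfg$synth$radius_range,
        overlap_fraction = cfg$synth$overlap_fraction,
        border_fraction = cfg$synth$border_fraction,
        noise_sd = cfg$synth$noise_sd,
        seed = cfg$seed * 1000L + i))
      write_scene(sc, scenes_dir, sprintf("scene%03d", i))
      sc
    })
  }, error = on_stage_error("synth"))
  finish_stage("synth", list.files(scenes_dir, full.names = TRUE),
               seed = cfg$seed, params = cfg$synth)

  # 2. normalize
  say("stage normalize")
  norm_dir <- file.path(out_dir, "normalized")
  dir.create(norm_dir, showWarnings = FALSE)
  ref <- reference_stain_profile()
  normalized <- tryCatch(lapply(seq_along(scenes), function(i) {
    img <- normalize_to_reference(scenes[[i]]$image, reference = ref)
    write_rgb(img, file.path(norm_dir, sprintf("scene%03d.png", i)))
    img
  }), error = on_stage_error("normalize"))
  finish_stage("normalize", list.files(norm_dir, full.names = TRUE))

  # 3. foreground
  say("stage foreground")
  fg_dir <- file.path(out_dir, "foreground")
  dir.create(fg_dir, showWarnings = FALSE)
  foregrounds <- tryCatch(lapply(seq_along(normalized), function(i) {
    fg <- compute_foreground_mask(enhance_contrast(normalized[[i]]),
                                  local_block = cfg$foreground$local_block,
                                  min_hole = cfg$foreground$min_hole,
                                  open_radius = cfg$foreground$open_radius)
    write_mask(fg * 1L, file.path(fg_dir, sprintf("scene%03d.tiff", i)))
    fg
  }), error = on_stage_error("foreground"))
  finish_stage("foreground", list.files(fg_dir, full.names = TRUE),
               params = cfg$foreground)

  # train/test split
  n_test <- max(1, round(cfg$split$test_fraction * length(scenes)))
  test_idx <- seq(length(scenes) - n_test + 1, length(scenes))
  train_idx <- setdiff(seq_along(scenes), test_idx)

  # 4. pseudolabel (training scenes only)
  say("stage pseudolabel")
  pl_dir <- file.path(out_dir, "pseudolabels")
  dir.create(pl_dir, showWarnings = FALSE)
  pseudolabels <- tryCatch(lapply(train_idx, function(i) {
    pl <- pseudo_label(normalized[[i]],
                       segmenter = function(img, fg)
                         watershed_baseline(img, fg,
                                            h = cfg$pseudolabel$marker_sep),
                       foreground = foregrounds[[i]],
                       min_area = cfg$pseudolabel$min_area)
    write_mask(pl, file.path(pl_dir, sprintf("scene%03d.tiff", i)))
    pl
  }), error = on_stage_error("pseudolabel"))
  finish_stage("pseudolabel", list.files(pl_dir, full.names = TRUE),
               params = cfg$pseudolabel)

  # 5. patchify
  say("stage patchify")
  patch_dir <- file.path(out_dir, "patches")
  dir.create(patch_dir, showWarnings = FALSE)
  patches <- tryCatch({
    ps <- list()
    for (j in seq_along(train_idx)) {
      i <- train_idx[j]
      ps <- c(ps, patchify(normalized[[i]], pseudolabels[[j]],
                           patch_size = cfg$patchify$patch_size,
                           stride = cfg$patchify$stride,
                           min_foreground = cfg$patchify$min_foreground,
                           source_id = sprintf("scene%03d", i)))
    }
    idx <- data.frame(patch = seq_along(ps),
                      source_id = vapply(ps, `[[`, "", "source_id"),
                      row = vapply(ps, function(p) p$offset[1], numeric(1)),
                      col = vapply(ps, function(p) p$offset[2], numeric(1)))
    write.csv(idx, file.path(patch_dir, "index.csv"), row.names = FALSE)
    ps
  }, error = on_stage_error("patchify"))
  finish_stage("patchify", file.path(patch_dir, "index.csv"),
               params = cfg$patchify)

  # 6. train
  say("stage train: %d patches, %d epochs", length(patches),
      cfg$train$epochs)
  tc <- do.call(train_config,
                c(cfg$train, list(patch_size = cfg$patchify$patch_size,
                                  seed = cfg$seed)))
  fit <- tryCatch({
    f <- train_predictor(patches, tc)
    f$predictor <- optimize_thresholds(f$predictor, patches[f$val_idx],
                                       iou_grid = c(0.3, 0.4))
    f
  }, error = on_stage_error("train"))
  ckpt <- file.path(out_dir, "checkpoint.rds")
  save_predictor(fit$predictor, ckpt, record = fit$record)
  write.csv(fit$record, file.path(out_dir, "training_record.csv"),
            row.names = FALSE)
  finish_stage("train", c(ckpt, file.path(out_dir, "training_record.csv")),
               seed = cfg$seed, params = cfg$train)

  # 7. predict (held-out scenes, no preprocessing)
  say("stage predict: %d held-out scenes", length(test_idx))
  det_dir <- file.path(out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE)
  detections <- tryCatch(lapply(test_idx, function(i) {
    det <- predict_image(scenes[[i]]$image, fit$predictor,
                         prob_thresh = cfg$predict$prob_thresh,
                         iou_thresh = cfg$predict$iou_thresh,
                         tile = cfg$predict$tile,
                         overlap = cfg$predict$overlap)
    write_mask(det$instance_mask,
               file.path(det_dir, sprintf("scene%03d.tiff", i)))
    write_detections_csv(det, sprintf("scene%03d", i),
                         file.path(det_dir, sprintf("scene%03d.csv", i)))
    det
  }), error = on_stage_error("predict"))
  finish_stage("predict", list.files(det_dir, full.names = TRUE),
               params = cfg$predict)

  # 8. evaluate
  say("stage evaluate")
  rows <- tryCatch({
    do.call(rbind, lapply(seq_along(test_idx), function(j) {
      i <- test_idx[j]
      m <- match_instances(detections[[j]]$instance_mask, scenes[[i]]$mask,
                           cfg$evaluate$iou_thresh)
      detection_metrics(m, sprintf("scene%03d", i))
    }))
  }, error = on_stage_error("evaluate"))
  report <- aggregate_report(rows)
  write_report_csv(report, file.path(out_dir, "report.csv"))
  finish_stage("evaluate", file.path(out_dir, "report.csv"),
               params = cfg$evaluate)
  say("pipeline complete: mean F1 %.2f", report$summary$mean[3])
  invisible(out_dir)
}

write_scene <- function(scene, dir, name) {
  write_rgb(scene$image, file.path(dir, paste0(name, "_image.png")))
  write_mask(scene$mask, file.path(dir, paste0(name, "_mask.tiff")))
  write.csv(scene$nuclei, file.path(dir, paste0(name, "_nuclei.csv")),
            row.names = FALSE)
  cfg <- scene$config
  cfg$stain_matrix <- as.vector(t(cfg$stain_matrix))
  jsonlite::write_json(unclass(cfg), file.path(dir, paste0(name, "_scene.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write a detection set as CSV (one row per instance)
#'
#' Columns: `image_id`, `instance`, `row`, `col`, `score`, followed by
#' the polygon radii.
#'
#' @param detections A `detection_set`.
#' @param image_id Identifier column value.
#' @param path Output path.
#' @export
write_detections_csv <- function(detections, image_id, path) {
  n <- nrow(detections$centroids)
  radii <- detections$polygons$radii
  df <- data.frame(image_id = rep(image_id, n),
                   instance = seq_len(n),
                   row = detections$centroids[, 1],
                   col = detections$centroids[, 2],
                   score = detections$polygons$scores)
  if (n > 0 && !is.null(radii) && ncol(radii) > 0) {
    radii <- as.data.frame(radii)
    names(radii) <- paste0("r", seq_len(ncol(radii)))
    df <- cbind(df, radii)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_report_csv <- function(report, path) {
  rows <- report$rows
  tail_rows <- data.frame(image_id = c("mean", "sd"), gt = NA, tp = NA,
                          fp = NA, fn = NA,
                          recall = c(report$summary$mean[1], report$summary$sd[1]),
                          precision = c(report$summary$mean[2], report$summary$sd[2]),
                          f1 = c(report$summary$mean[3], report$summary$sd[3]))
  write.csv(rbind(rows, tail_rows), path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(x) {
  if (is.null(x)) return(NULL)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

file_hashes <- function(paths) {
  paths <- unlist(paths)
  lapply(seq_along(paths), function(i)
    list(file = basename(paths[i]), md5 = unname(tools::md5sum(paths[i]))))
}
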