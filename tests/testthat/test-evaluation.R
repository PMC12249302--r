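test_that("instance matching handles identity and split nuclei", {
  mask <- random_blob_mask(1, H = 30, W = 30, n = 3)
  m <- match_instances(mask, mask, 0.5)
  expect_identical(m$tp, 3L)
  expect_identical(m$fp, 0L); expect_identical(m$fn, 0L)
  # one ground-truth nucleus split into two predictions
  gt <- matrix(0L, 20, 20); gt[5:16, 5:16] <- 1L
  pred <- matrix(0L, 20, 20)
  pred[5:16, 5:10] <- 1L; pred[5:16, 11:16] <- 2L
  ms <- match_instances(pred, gt, 0.4)
  expect_identical(ms$tp, 1L)
  expect_identical(ms$fp, 1L)
  expect_identical(ms$fn, 0L)
  expect_error(match_instances(pred, gt[1:10, ]), "shape")
})

test_that("instance matching equals exhaustive assignment on small cases", {
  for (seed in 1:8) {
    pred <- random_blob_mask(seed, H = 26, W = 26, n = 3)
    gt <- random_blob_mask(seed + 100, H = 26, W = 26, n = 3)
    for (thr in c(0.3, 0.5)) {
      got <- match_instances(pred, gt, thr)
      ora <- oracle_match(pred, gt, thr)
      expect_identical(got$tp, as.integer(ora$tp))
      expect_identical(got$fp, as.integer(ora$fp))
      expect_identical(got$fn, as.integer(ora$fn))
      # swapping pred and gt swaps fp and fn with tp unchanged
      sw <- match_instances(gt, pred, thr)
      expect_identical(sw$tp, got$tp)
      expect_identical(sw$fp, got$fn)
      expect_identical(sw$fn, got$fp)
    }
  }
})

test_that("point matching follows containment and nearest-centroid rules", {
  inst <- matrix(0L, 30, 30)
  inst[5:12, 5:12] <- 1L
  inst[18:26, 16:26] <- 2L
  det <- list(instance_mask = inst,
              centroids = rbind(c(8.5, 8.5), c(22, 21)))
  # each point in its own instance
  m <- match_points(det, rbind(c(8, 8), c(20, 20)))
  expect_identical(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  # a background point is a miss
  m2 <- match_points(det, rbind(c(8, 8), c(1, 29)))
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 1L))
  # two points in one instance: nearest centroid wins, the other is FN
  m3 <- match_points(det, rbind(c(8, 8), c(9, 9), c(22, 21)))
  expect_identical(c(m3$tp, m3$fp, m3$fn), c(2L, 0L, 1L))
  expect_true(all(m3$pairs[m3$pairs[, 1] == 1, 2] == 1))
  # tp + fn equals the number of points in every case
  for (mm in list(m, m2, m3))
    expect_identical(mm$tp + mm$fn, c(2L, 2L, 3L)[which(
      vapply(list(m, m2, m3), identical, logical(1), mm))])
  # region restriction: an unmatched prediction outside the region is ignored
  region <- matrix(FALSE, 30, 30); region[1:14, 1:14] <- TRUE
  m4 <- match_points(det, rbind(c(8, 8)), region = region)
  expect_identical(c(m4$tp, m4$fp, m4$fn), c(1L, 0L, 0L))
})

test_that("point matching equals a brute-force containment matcher", {
  for (seed in 1:6) {
    mask <- random_blob_mask(seed, H = 30, W = 30, n = 3)
    labs <- setdiff(unique(as.vector(mask)), 0)
    centroids <- t(vapply(labs, function(l) {
      px <- which(mask == l, arr.ind = TRUE); colMeans(px)
    }, numeric(2)))
    withr::with_seed(seed, pts <- cbind(sample(30, 4, TRUE), sample(30, 4, TRUE)))
    got <- match_points(list(instance_mask = mask, centroids = centroids), pts)
    # brute force: containment lookup + nearest centroid per instance
    labs_at <- mask[pts]
    tp <- 0
    for (l in setdiff(unique(labs_at), 0)) {
      tp <- tp + 1
    }
    fn <- nrow(pts) - tp
    fp <- length(labs) - length(setdiff(unique(labs_at), 0))
    expect_identical(got$tp, as.integer(tp))
    expect_identical(got$fn, as.integer(fn))
    expect_identical(got$fp, as.integer(fp))
  }
})

test_that("the expert filter applies all three criteria", {
  tab <- data.frame(label = 1:5,
                    red_signals = c(1, 2, 5, 3, 0),
                    overlaps_neighbor = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    touches_border = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  kept <- expert_filter(tab)
  expect_identical(kept$label, 2L) # only row 2 passes all criteria
  # random tables equal the row-by-row predicate
  withr::with_seed(4, {
    for (i in 1:5) {
      tb <- data.frame(red_signals = sample(0:5, 20, TRUE),
                       overlaps_neighbor = sample(c(TRUE, FALSE), 20, TRUE),
                       touches_border = sample(c(TRUE, FALSE), 20, TRUE))
      keep <- tb$red_signals >= 2 & !tb$overlaps_neighbor & !tb$touches_border
      expect_identical(expert_filter(tb), tb[keep, , drop = FALSE])
    }
  })
  expect_error(expert_filter(tab[, 1:2]), "columns")
})

test_that("metric formulas reproduce published worked examples", {
  r1 <- detection_metrics(list(tp = 143, fp = 3, fn = 3), "169284650")
  expect_identical(c(r1$recall, r1$precision, r1$f1), c(97.9, 97.9, 97.9))
  r2 <- detection_metrics(list(tp = 6, fp = 2, fn = 0), "169282117")
  expect_identical(c(r2$recall, r2$precision, r2$f1), c(100.0, 75.0, 85.7))
  r3 <- detection_metrics(list(tp = 10, fp = 0, fn = 0))
  expect_identical(c(r3$recall, r3$precision, r3$f1), c(100, 100, 100))
  expect_identical(r1$gt, 146L)
  expect_error(detection_metrics(list(tp = 0, fp = 0, fn = 0)), "undefined")
})

test_that("F1 is the harmonic mean of precision and recall before rounding", {
  withr::with_seed(10, {
    for (i in 1:50) {
      tp <- sample(0:200, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      if (tp + fp == 0 || tp + fn == 0) next
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      f1 <- 2 * tp / (2 * tp + fn + fp)
      hm <- if (p + r > 0) 2 * p * r / (p + r) else 0
      expect_equal(f1, hm)
    }
  })
})

test_that("aggregation uses rounded rows, mean to 2 and sd to 1 decimals", {
  rows <- do.call(rbind, lapply(1:3, function(i)
    detection_metrics(list(tp = c(9, 8, 7)[i], fp = c(1, 0, 2)[i],
                           fn = c(0, 2, 1)[i]), paste0("img", i))))
  rep <- aggregate_report(rows)
  expect_equal(rep$summary$mean[3], round(mean(rows$f1), 2))
  expect_equal(rep$summary$sd[3], round(sd(rows$f1), 1))
  single <- aggregate_report(rows[1, ])
  expect_equal(single$summary$mean[3], rows$f1[1])
  expect_equal(single$summary$sd[3], 0)
  expect_error(aggregate_report(rows[0, ]), "rows")
})

test_that("method comparison pools counts additively", {
  scenes <- lapply(c(91, 92), function(s)
    generate_scene(scene_config(height = 96, width = 96, n_nuclei = 6,
                                radius_range = c(6, 9),
                                overlap_fraction = 0, border_fraction = 0,
                                seed = s)))
  perfect <- function(scene) scene$mask
  tab <- compare_methods(list(truth = perfect, also_truth = perfect), scenes)
  expect_identical(tab$precision, c(100, 100))
  expect_identical(tab$recall, c(100, 100))
  expect_identical(tab$f1, c(100, 100))
  expect_identical(tab$tp[1], sum(vapply(scenes, function(s)
    max(s$mask), integer(1))))
  # pooled counts equal the sum of per-scene match results
  erode <- function(scene) remove_small_regions(scene$mask, 120)
  tab2 <- compare_methods(list(truth = perfect, eroded = erode), scenes)
  per_scene <- vapply(scenes, function(s) {
    m <- match_instances(erode(s), s$mask, 0.5)
    c(m$tp, m$fp, m$fn)
  }, numeric(3))
  expect_identical(tab2$tp[2], as.integer(sum(per_scene[1, ])))
  expect_identical(tab2$fn[2], as.integer(sum(per_scene[3, ])))
  expect_error(compare_methods(list(a = perfect), scenes), "2")
})
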