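test_that("radial distances of a centered disk are the radius within half a pixel", {
  m <- matrix(0L, 31, 31)
  m[(row(m) - 16)^2 + (col(m) - 16)^2 <= 100] <- 1L
  d <- compute_radial_distances(m, 32)
  expect_true(all(abs(d[16, 16, ] - 10) <= 0.5))
  expect_true(all(d[m == 0] == 0)) # background rows are zero on all rays
  expect_error(compute_radial_distances(m, 4), "n_rays")
})

test_that("radial distances equal the independent ray-marching oracle exactly", {
  for (seed in 1:5) {
    mask <- random_blob_mask(seed, H = 22, W = 24, n = 2)
    got <- compute_radial_distances(mask, 8)
    expect_identical(unname(got), unname(oracle_radial_distances(mask, 8)))
  }
})

test_that("object probability is an EDT normalized per instance", {
  mask <- random_blob_mask(3, H = 30, W = 30, n = 3)
  p <- compute_object_probability(mask)
  expect_true(all(p[mask == 0] == 0))
  for (lab in setdiff(unique(as.vector(mask)), 0))
    expect_equal(max(p[mask == lab]), 1)
  # a disk's probability decreases with distance from the center
  m <- matrix(0L, 25, 25)
  m[(row(m) - 13)^2 + (col(m) - 13)^2 <= 64] <- 1L
  pd <- compute_object_probability(m)
  rho <- sqrt((row(m) - 13)^2 + (col(m) - 13)^2)
  inside <- m == 1
  bins <- split(pd[inside], round(rho[inside]))
  expect_true(all(diff(vapply(bins, mean, numeric(1))) < 0))
})

test_that("dist and prob ground truth are translation equivariant", {
  mask <- matrix(0L, 40, 40)
  blob <- make_star_convex_blob(c(12, 12), 6, 0.3, seed = 4, shape = c(40, 40))
  mask[blob] <- 1L
  shifted <- matrix(0L, 40, 40)
  shifted[7:40, 5:40] <- mask[1:34, 1:36]
  d1 <- compute_radial_distances(mask, 8)
  d2 <- compute_radial_distances(shifted, 8)
  expect_equal(d2[7:34, 5:36, ], d1[1:28, 1:32, ])
  p1 <- compute_object_probability(mask)
  p2 <- compute_object_probability(shifted)
  expect_equal(p2[7:34, 5:36], p1[1:28, 1:32])
})

test_that("polygon IoU matches the independent rasterizer on random pairs", {
  withr::with_seed(99, {
    for (i in 1:12) {
      ca <- runif(2, 8, 14); cb <- ca + runif(2, -6, 6)
      ra <- runif(8, 2, 6); rb <- runif(8, 2, 6)
      got <- polygon_iou(list(center = ca, radii = ra),
                         list(center = cb, radii = rb))
      expect_equal(got, oracle_polygon_iou(ca, ra, cb, rb), tolerance = 1e-12)
    }
  })
  a <- list(center = c(10, 10), radii = rep(4, 8))
  expect_equal(polygon_iou(a, a), 1)
  far <- list(center = c(40, 40), radii = rep(4, 8))
  expect_equal(polygon_iou(a, far), 0)
  empty <- list(center = c(10, 10), radii = rep(0, 8))
  expect_equal(polygon_iou(empty, empty), 0) # empty-by-convention
})

test_that("candidate extraction counts super-threshold pixels", {
  withr::with_seed(2, {
    prob <- matrix(runif(100), 10)
    dist <- array(runif(800, 1, 5), c(10, 10, 8))
  })
  cands <- candidate_polygons(prob, dist, 0.6)
  expect_identical(length(cands$scores), sum(prob > 0.6))
  expect_true(all(cands$scores > 0.6))
  one <- candidate_polygons(matrix(c(0.9, rep(0.1, 8)), 3),
                            array(2, c(3, 3, 8)), 0.5)
  expect_identical(length(one$scores), 1L)
  expect_identical(one$centers, cbind(1L, 1L))
  none <- candidate_polygons(matrix(0.2, 4, 4), array(1, c(4, 4, 8)), 0.5)
  expect_identical(length(none$scores), 0L)
})

test_that("greedy NMS equals the sequential oracle on random candidate sets", {
  withr::with_seed(123, {
    for (i in 1:10) {
      n <- sample(2:8, 1)
      centers <- cbind(runif(n, 8, 20), runif(n, 8, 20))
      radii <- matrix(runif(n * 8, 2, 6), n)
      scores <- runif(n)
      thr <- runif(1, 0.2, 0.6)
      got <- greedy_nms(list(centers = centers, radii = radii,
                             scores = scores), thr)
      expect_identical(got$kept_index, oracle_nms(centers, radii, scores, thr))
      # kept set is pairwise sub-threshold
      k <- length(got$scores)
      if (k > 1) {
        for (a in 1:(k - 1)) for (b in (a + 1):k) {
          expect_lt(polygon_iou(list(center = got$centers[a, ],
                                     radii = got$radii[a, ]),
                                list(center = got$centers[b, ],
                                     radii = got$radii[b, ])), thr)
        }
      }
      # result invariant to input permutation
      perm <- sample(n)
      got2 <- greedy_nms(list(centers = centers[perm, , drop = FALSE],
                              radii = radii[perm, , drop = FALSE],
                              scores = scores[perm]), thr)
      expect_identical(perm[got2$kept_index], got$kept_index)
    }
  })
})

test_that("NMS keeps the best of two identical polygons and validates thresholds", {
  cands <- list(centers = rbind(c(20, 20), c(20, 20)),
                radii = rbind(rep(8, 16), rep(8, 16)),
                scores = c(0.9, 0.8))
  k <- greedy_nms(cands, 0.4)
  expect_identical(k$scores, 0.9)
  single <- greedy_nms(list(centers = rbind(c(5, 5)),
                            radii = matrix(3, 1, 8), scores = 0.7), 0.4)
  expect_identical(single$kept_index, 1L)
  expect_error(greedy_nms(cands, 1.2), "iou_thresh")
})

test_that("rasterized detections resolve overlaps by score and renumber", {
  kept <- list(centers = rbind(c(15, 15), c(15, 22)),
               radii = rbind(rep(6, 16), rep(6, 16)),
               scores = c(0.95, 0.6))
  ds <- rasterize_detections(kept, c(30, 40))
  # contested pixels carry the higher-score label (instance 1)
  mid <- ds$instance_mask[15, 18]
  expect_identical(mid, 1L)
  expect_identical(sort(unique(as.vector(ds$instance_mask))), c(0L, 1L, 2L))
  # non-overlapping polygons keep their solo raster area
  kept2 <- list(centers = rbind(c(10, 10), c(10, 30)),
                radii = rbind(rep(4, 16), rep(5, 16)),
                scores = c(0.8, 0.7))
  ds2 <- rasterize_detections(kept2, c(20, 45))
  solo1 <- sum(rasterize_polygon(c(10, 10), rep(4, 16), c(20, 45)))
  solo2 <- sum(rasterize_polygon(c(10, 30), rep(5, 16), c(20, 45)))
  areas <- tabulate(ds2$instance_mask[ds2$instance_mask > 0])
  expect_identical(areas, c(solo1, solo2))
  # empty input
  none <- rasterize_detections(list(centers = matrix(numeric(0), 0, 2),
                                    radii = matrix(numeric(0), 0, 16),
                                    scores = numeric(0)), c(10, 10))
  expect_identical(max(none$instance_mask), 0L)
  expect_identical(nrow(none$centroids), 0L)
})

test_that("disks of radius >= 5 reconstruct from their center polygon", {
  for (rad in 5:14) {
    H <- 2 * rad + 13
    ctr <- c((H + 1) / 2, (H + 1) / 2)
    disk <- matrix(0L, H, H)
    disk[(row(disk) - ctr[1])^2 + (col(disk) - ctr[2])^2 <= rad^2] <- 1L
    radii <- compute_radial_distances(disk, 32)[ctr[1], ctr[2], ]
    poly <- rasterize_polygon(ctr, radii, c(H, H))
    iou <- sum(poly & disk > 0) / sum(poly | disk > 0)
    expect_gte(iou, 0.95)
  }
})
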