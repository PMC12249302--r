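test_that("zero irregularity gives the exact rasterized disk", {
  for (rad in c(3, 5.5, 9)) {
    b <- make_star_convex_blob(c(15, 16), rad, 0, seed = 1, shape = c(31, 31))
    disk <- (row(b) - 15)^2 + (col(b) - 16)^2 <= rad^2 + 1e-9
    expect_identical(b, disk)
  }
})

test_that("blob masks are star-convex: every one-degree ray exits once", {
  # the underlying region is an exact radial function; on the rasterized
  # mask a sampled ray may flicker within the one-pixel aliasing band at
  # the boundary, so the check is: each ray exits, and no inside sample
  # exists beyond 1.5 px past its first exit
  for (seed in 1:8) {
    ctr <- c(20, 20)
    b <- make_star_convex_blob(ctr, 8, 0.4, seed = seed, shape = c(40, 40))
    expect_true(b[ctr[1], ctr[2]])
    for (deg in seq(0, 359, by = 1)) {
      th <- deg * pi / 180
      ts <- seq(0.25, 16, by = 0.25)
      ins <- vapply(ts, function(t) {
        rr <- floor(ctr[1] + t * sin(th) + 0.5)
        cc <- floor(ctr[2] + t * cos(th) + 0.5)
        rr >= 1 && rr <= 40 && cc >= 1 && cc <= 40 && b[rr, cc]
      }, logical(1))
      first_exit <- ts[which(!ins)[1]]
      expect_false(is.na(first_exit)) # ray must exit
      later_inside <- ts[ins & ts > first_exit]
      if (length(later_inside))
        expect_lte(max(later_inside) - first_exit, 1.5)
    }
  }
})

test_that("blob generation is deterministic and validates inputs", {
  b1 <- make_star_convex_blob(c(10, 10), 5, 0.3, seed = 7, shape = c(21, 21))
  b2 <- make_star_convex_blob(c(10, 10), 5, 0.3, seed = 7, shape = c(21, 21))
  expect_identical(b1, b2)
  expect_gt(sum(b1), 0)
  expect_error(make_star_convex_blob(c(10, 10), 5, 0.7, seed = 1),
               "irregularity")
  expect_error(make_star_convex_blob(c(10, 10), 2, 0, seed = 1),
               "mean_radius")
})

test_that("scenes carry consistent ground truth metadata", {
  for (seed in c(3, 17, 90)) {
    cfg <- scene_config(height = 128, width = 128, n_nuclei = 14,
                        radius_range = c(5, 8), overlap_fraction = 0.2,
                        border_fraction = 0.15, seed = seed)
    sc <- generate_scene(cfg)
    labs <- sort(setdiff(unique(as.vector(sc$mask)), 0))
    expect_identical(labs, 1:14) # consecutive labels from 1
    expect_identical(nrow(sc$nuclei), 14L)
    for (i in labs) {
      px <- which(sc$mask == i, arr.ind = TRUE)
      expect_equal(sc$nuclei$row[i], mean(px[, 1]))
      expect_equal(sc$nuclei$col[i], mean(px[, 2]))
      expect_identical(sc$nuclei$area[i], nrow(px))
      touches <- any(px[, 1] %in% c(1, 128) | px[, 2] %in% c(1, 128))
      expect_identical(sc$nuclei$touches_border[i], touches)
    }
    expect_true(any(sc$nuclei$touches_border))
    expect_true(any(sc$nuclei$overlaps_neighbor))
    expect_true(all(sc$image >= 0 & sc$image <= 255))
  }
})

test_that("scene generation is a pure function of its config", {
  cfg <- scene_config(height = 96, width = 96, n_nuclei = 8,
                      radius_range = c(5, 8), seed = 5)
  a <- generate_scene(cfg); b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$nuclei, b$nuclei)
})

test_that("an empty scene renders background only", {
  sc <- generate_scene(scene_config(height = 64, width = 64, n_nuclei = 0,
                                    overlap_fraction = 0,
                                    border_fraction = 0, seed = 1))
  expect_identical(max(sc$mask), 0L)
  expect_identical(nrow(sc$nuclei), 0L)
  # pale background, roughly at the configured intensity
  expect_gt(mean(sc$image), 200)
})

test_that("border_fraction = 0 places no nucleus on the border", {
  sc <- generate_scene(scene_config(height = 160, width = 160, n_nuclei = 12,
                                    radius_range = c(5, 8),
                                    overlap_fraction = 0,
                                    border_fraction = 0, seed = 21))
  expect_false(any(sc$nuclei$touches_border))
  expect_identical(max(sc$mask), 12L)
})

test_that("infeasible placements raise a generation error naming the role", {
  cfg <- scene_config(height = 64, width = 64, n_nuclei = 30,
                      radius_range = c(10, 12), overlap_fraction = 0,
                      border_fraction = 0, seed = 1)
  expect_error(generate_scene(cfg), "placement failed")
})

test_that("config invariants are enforced", {
  expect_error(scene_config(radius_range = c(2, 5)), "radius_range")
  expect_error(scene_config(overlap_fraction = 0.7, border_fraction = 0.5),
               "overlap_fraction")
  bad <- sish_stain_matrix(); bad[1, 1] <- bad[1, 1] * 2
  expect_error(scene_config(stain_matrix = bad), "unit L2 norm")
})
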