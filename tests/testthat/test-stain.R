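test_that("optical density transform matches its closed form and round-trips", {
  img <- array(c(255, 25.5, 128, 1, 64, 200), c(1, 2, 3))
  od <- rgb_to_od(img, i0 = 255)
  expect_equal(od[1, 1, 1], 0) # white point
  expect_equal(rgb_to_od(array(25.5, c(1, 1, 3)))[1, 1, 1], 1) # -log10(0.1)
  # round trip within one intensity step for random integer images
  withr::with_seed(42, {
    x <- array(sample(1:255, 300, replace = TRUE), c(10, 10, 3))
    back <- od_to_rgb(rgb_to_od(x))
    expect_lte(max(abs(back - x)), 1)
  })
})

test_that("stain vectors are recovered from noise-free renders", {
  for (seed in 1:3) {
    cfg <- scene_config(height = 128, width = 128, n_nuclei = 12,
                        radius_range = c(6, 9), noise_sd = 0, seed = seed)
    sc <- generate_scene(cfg)
    prof <- estimate_stain_profile(rgb_to_od(sc$image))
    expect_lt(stain_angle(prof$vectors[, 1], cfg$stain_matrix[, 1]), 5)
    expect_lt(stain_angle(prof$vectors[, 2], cfg$stain_matrix[, 2]), 5)
    expect_true(all(abs(colSums(prof$vectors^2) - 1) < 1e-8))
    expect_true(all(prof$max_concentrations > 0))
  }
})

test_that("a single pure stain yields a rank-1 OD cloud along its direction", {
  v <- sish_stain_matrix()[, 1]
  conc <- seq(0.3, 1.2, length.out = 400)
  od_px <- outer(conc, v) # 400 x 3
  img <- od_to_rgb(array(t(od_px), c(3, 20, 20)) |> aperm(c(2, 3, 1)))
  prof <- try(estimate_stain_profile(rgb_to_od(img)), silent = TRUE)
  # with one stain both percentile angles collapse onto its direction
  expect_false(inherits(prof, "try-error"))
  expect_lt(stain_angle(prof$vectors[, 1], v), 2)
})

test_that("doubling optical density doubles concentrations, not vectors", {
  sc <- generate_scene(scene_config(height = 96, width = 96, n_nuclei = 8,
                                    radius_range = c(6, 9), noise_sd = 0,
                                    seed = 12))
  od <- rgb_to_od(sc$image)
  p1 <- estimate_stain_profile(od)
  od2 <- od * 2
  attr(od2, "i0") <- attr(od, "i0")
  p2 <- estimate_stain_profile(od2)
  expect_lt(stain_angle(p1$vectors[, 1], p2$vectors[, 1]), 0.5)
  expect_lt(stain_angle(p1$vectors[, 2], p2$vectors[, 2]), 0.5)
  expect_equal(p2$max_concentrations, 2 * p1$max_concentrations,
               tolerance = 0.02)
})

test_that("estimation fails cleanly without enough tissue", {
  img <- array(250L, c(20, 20, 3)) # blank, everything below beta
  expect_error(estimate_stain_profile(rgb_to_od(img)), "tissue pixels")
})

test_that("normalizing to the image's own profile is near-identity", {
  sc <- generate_scene(scene_config(height = 96, width = 96, n_nuclei = 8,
                                    radius_range = c(6, 9), noise_sd = 0,
                                    seed = 9))
  p <- estimate_stain_profile(rgb_to_od(sc$image))
  out <- normalize_to_reference(sc$image, source = p, reference = p)
  d <- abs(out - sc$image)
  # zero-clipped unmixing perturbs only the few off-cone extreme pixels
  expect_lte(max(d), 2)
  expect_gt(mean(d <= 1), 0.99)
})

test_that("normalization is idempotent within quantization", {
  ref <- reference_stain_profile()
  sc <- generate_scene(scene_config(height = 96, width = 96, n_nuclei = 8,
                                    radius_range = c(6, 9), noise_sd = 3,
                                    seed = 11))
  n1 <- normalize_to_reference(sc$image, reference = ref)
  n2 <- normalize_to_reference(n1, reference = ref)
  d <- abs(n2 - n1)
  expect_lte(mean(d), 0.5)
  expect_gt(mean(d <= 2), 0.999)
})

test_that("re-estimated vectors after normalization match the reference", {
  ref <- reference_stain_profile()
  cfg <- scene_config(height = 128, width = 128, n_nuclei = 12,
                      radius_range = c(6, 9), noise_sd = 0, seed = 31)
  sc <- generate_scene(cfg)
  shifted <- render_scene(sc, shifted_stain_matrix(cfg$stain_matrix, -12),
                          noise_sd = 0, conc_scale = c(0.8, 1.3))
  norm <- normalize_to_reference(shifted, reference = ref)
  p2 <- estimate_stain_profile(rgb_to_od(norm))
  expect_lt(stain_angle(p2$vectors[, 1], ref$vectors[, 1]), 5)
  expect_lt(stain_angle(p2$vectors[, 2], ref$vectors[, 2]), 5)
})

test_that("ssim satisfies its closed forms", {
  withr::with_seed(5, x <- matrix(runif(400, 0, 255), 20))
  expect_equal(ssim(x, x), 1)
  # uniform images: contrast/structure terms are 1
  mu_a <- 120; mu_b <- 180; C1 <- (0.01 * 255)^2
  a <- matrix(mu_a, 12, 12); b <- matrix(mu_b, 12, 12)
  expect_equal(ssim(a, b), (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1))
  expect_error(ssim(x, x[1:10, ]), "same shape")
})

test_that("ssim equals the direct windowed formula on toy gradients", {
  g <- outer(seq(0, 255, length.out = 16), seq(0, 255, length.out = 16),
             function(a, b) (a + b) / 2)
  withr::with_seed(8, h <- g + matrix(rnorm(256, 0, 12), 16))
  expect_equal(ssim(g, h), oracle_ssim(g, h), tolerance = 1e-12)
})

test_that("stain profiles serialize through JSON losslessly", {
  prof <- reference_stain_profile()
  path <- tempfile(fileext = ".json")
  write_stain_profile(prof, path)
  back <- read_stain_profile(path)
  expect_equal(back$vectors, prof$vectors)
  expect_equal(back$max_concentrations, prof$max_concentrations)
})
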