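#' Synthetic SISH scene configuration
#'
#' Describes a synthetic silver in situ hybridization (SISH) scene:
#' bluish-purple star-convex nuclei on a pale tissue background, with
#' black HER2 and red CEN17 dot signals rendered inside nuclei through a
#' known 3x2 optical-density stain matrix, so that stain estimation can
#' be validated against the generating basis.
#'
#' @param height,width Scene size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range Length-2 numeric, min/max mean nucleus radius (px).
#' @param overlap_fraction Proportion of nuclei placed to overlap a
#'   neighbour.
#' @param border_fraction Proportion of nuclei placed touching the image
#'   border.
#' @param red_signal_range Length-2 integer, min/max red (CEN17) dots per
#'   nucleus.
#' @param black_signal_range Length-2 integer, min/max black (HER2) dots
#'   per nucleus.
#' @param stain_matrix 3x2 matrix of unit-norm optical-density stain
#'   vectors (column 1: nuclear counterstain, column 2: red signal stain).
#' @param background_intensity Approximate background brightness (0-255).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param irregularity Radial irregularity of nucleus outlines in
#'   \[0, 0.5\].
#' @param seed Integer seed; scenes are a pure function of the config.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(height = 256, width = 256, n_nuclei = 40,
                         radius_range = c(8, 14),
                         overlap_fraction = 0.15, border_fraction = 0.10,
                         red_signal_range = c(1, 6),
                         black_signal_range = c(2, 10),
                         stain_matrix = sish_stain_matrix(),
                         background_intensity = 235, noise_sd = 3,
                         irregularity = 0.25, seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_nuclei = as.integer(n_nuclei),
              radius_range = as.numeric(radius_range),
              overlap_fraction = overlap_fraction,
              border_fraction = border_fraction,
              red_signal_range = as.integer(red_signal_range),
              black_signal_range = as.integer(black_signal_range),
              stain_matrix = stain_matrix,
              background_intensity = background_intensity,
              noise_sd = noise_sd, irregularity = irregularity,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$height >= 32, cfg$width >= 32, cfg$n_nuclei >= 0)
  if (cfg$radius_range[1] < 3)
    stop("radius_range minimum must be >= 3 pixels")
  if (cfg$overlap_fraction < 0 || cfg$border_fraction < 0 ||
      cfg$overlap_fraction + cfg$border_fraction > 1)
    stop("overlap_fraction + border_fraction must lie in [0, 1]")
  if (cfg$irregularity < 0 || cfg$irregularity > 0.5)
    stop("irregularity must lie in [0, 0.5]")
  m <- cfg$stain_matrix
  if (!is.matrix(m) || any(dim(m) != c(3, 2)) || any(m < 0))
    stop("stain_matrix must be a non-negative 3x2 matrix")
  if (any(abs(sqrt(colSums(m^2)) - 1) > 1e-6))
    stop("stain_matrix columns must have unit L2 norm")
  invisible(cfg)
}

#' Default SISH stain basis
#'
#' Unit-norm optical-density vectors for the two synthetic stains: a
#' bluish-purple nuclear counterstain (absorbs red/green) and a red
#' signal stain (absorbs green/blue).
#'
#' @return A 3x2 matrix with unit-norm columns.
#' @export
sish_stain_matrix <- function() {
  m <- cbind(c(0.650, 0.704, 0.286), c(0.216, 0.801, 0.558))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Rotate a stain basis within the red-green optical-density plane
#'
#' Produces a stain-shifted variant of a basis, emulating inter-slide
#' hue variation. Negative angles increase the red-channel OD
#' components, keeping both stains above typical transparency
#' thresholds.
#'
#' @param stain_matrix 3x2 unit-column stain basis.
#' @param degrees Rotation angle in degrees.
#' @return Rotated, re-normalized 3x2 basis.
#' @export
shifted_stain_matrix <- function(stain_matrix, degrees) {
  th <- degrees * pi / 180
  rot <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  m <- rot %*% stain_matrix
  m <- pmax(m, 0)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Smooth periodic radial perturbation, normalized to max |s| = 1.
radial_profile <- function(n_harmonics = 3) {
  amp <- runif(n_harmonics, 0.3, 1) / (2:(n_harmonics + 1))
  phase <- runif(n_harmonics, 0, 2 * pi)
  f <- function(theta) {
    s <- 0
    for (m in seq_len(n_harmonics))
      s <- s + amp[m] * cos((m + 1) * theta + phase[m])
    s
  }
  # normalize on a fine grid
  grid <- f(seq(0, 2 * pi, length.out = 720))
  peak <- max(abs(grid))
  if (peak < 1e-9) return(function(theta) 0 * theta)
  function(theta) f(theta) / peak
}

#' Generate a star-convex blob mask
#'
#' Rasterizes a star-convex region: the boundary is a smooth radial
#' function `r(theta) = mean_radius * (1 + irregularity * s(theta))`
#' around the given center, so every ray from the center crosses the
#' boundary exactly once. With `irregularity = 0` the result is the
#' exact rasterized disk of radius `mean_radius`.
#'
#' @param center Length-2 numeric (row, col), 1-based pixel coordinates.
#' @param mean_radius Mean radius in pixels (>= 3).
#' @param irregularity Perturbation amplitude in \[0, 0.5\].
#' @param seed Integer seed controlling the boundary shape.
#' @param shape Length-2 integer (rows, cols) of the output mask.
#' @return A logical matrix of dimension `shape`.
#' @export
make_star_convex_blob <- function(center, mean_radius, irregularity, seed,
                                  shape = ceiling(c(center[1], center[2]) +
                                                  mean_radius * (1 + irregularity) + 1)) {
  if (mean_radius < 3) stop("mean_radius must be >= 3")
  if (irregularity < 0 || irregularity > 0.5)
    stop("irregularity must lie in [0, 0.5]")
  prof <- withr::with_seed(as.integer(seed), radial_profile())
  rasterize_radial(center, function(theta)
    mean_radius * (1 + irregularity * prof(theta)), shape)
}

# Rasterize { p : |p - center| <= rfun(angle(p)) } on a 1-based pixel grid.
rasterize_radial <- function(center, rfun, shape) {
  H <- shape[1]; W <- shape[2]
  rmax <- max(rfun(seq(0, 2 * pi, length.out = 720)))
  r0 <- max(1, floor(center[1] - rmax)); r1 <- min(H, ceiling(center[1] + rmax))
  c0 <- max(1, floor(center[2] - rmax)); c1 <- min(W, ceiling(center[2] + rmax))
  out <- matrix(FALSE, H, W)
  if (r1 < r0 || c1 < c0) return(out)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  out[rows, cols] <- rho <= rfun(theta) + 1e-9
  out
}

#' Generate a synthetic SISH scene with full ground truth
#'
#' Places star-convex nuclei (free-standing, overlapping, and
#' border-touching according to the configured fractions) by rejection
#' sampling, paints them into an instance mask where later nuclei win
#' contested pixels, scatters red and black dot signals inside nuclei,
#' and renders the scene through the configured stain matrix via the
#' inverse optical-density transform plus Gaussian noise.
#'
#' @param config A [scene_config()].
#' @return An object of class `sish_scene`: a list with `image`
#'   (H x W x 3 integer array, 0-255), `mask` (H x W integer instance
#'   mask), `nuclei` (per-nucleus metadata data frame), concentration
#'   maps `conc1`/`conc2` (for re-rendering through other stain bases),
#'   and the `config`.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  H <- cfg$height; W <- cfg$width; n <- cfg$n_nuclei
  n_border <- round(cfg$border_fraction * n)
  n_overlap <- round(cfg$overlap_fraction * n)
  n_free <- n - n_border - n_overlap
  roles <- c(rep("free", n_free), rep("overlap", n_overlap),
             rep("border", n_border))

  radii <- runif(n, cfg$radius_range[1], cfg$radius_range[2])
  rmax <- radii * (1 + cfg$irregularity)
  blob_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1))
  centers <- matrix(NA_real_, n, 2)
  blobs <- vector("list", n)

  place_fail <- function(role)
    stop(sprintf("scene placement failed: could not place a '%s' nucleus under the spacing constraints", role))

  for (i in seq_len(n)) {
    role <- roles[i]
    placed <- FALSE
    for (try in seq_len(300)) {
      if (role == "free" || (role == "overlap" && i == 1)) {
        m <- rmax[i] + 2
        if (H - 2 * m <= 1 || W - 2 * m <= 1) next
        ctr <- c(runif(1, 1 + m, H - m), runif(1, 1 + m, W - m))
        ok <- all(sqrt((centers[seq_len(i - 1), 1] - ctr[1])^2 +
                       (centers[seq_len(i - 1), 2] - ctr[2])^2) >
                  rmax[i] + rmax[seq_len(i - 1)] + 2)
      } else if (role == "overlap") {
        j <- sample.int(i - 1, 1)
        ang <- runif(1, 0, 2 * pi)
        # shallow-to-moderate bite: with deeper overlap the z-order
        # partition would leave the occluded nucleus as a crescent,
        # which is no longer star-convex and so outside the data model
        d <- runif(1, 0.7, 0.9) * (radii[i] + radii[j])
        ctr <- centers[j, ] + d * c(sin(ang), cos(ang))
        m <- rmax[i] + 2
        ok <- ctr[1] > 1 + m && ctr[1] < H - m && ctr[2] > 1 + m && ctr[2] < W - m
      } else { # border
        edge <- sample(4, 1)
        off <- runif(1, -0.2, 0.5) * radii[i] # center close to/over the edge
        pos <- runif(1, 1 + rmax[i], max(H, W) - rmax[i])
        ctr <- switch(edge,
                      c(1 - off, min(pos, W - rmax[i])),
                      c(H + off, min(pos, W - rmax[i])),
                      c(min(pos, H - rmax[i]), 1 - off),
                      c(min(pos, H - rmax[i]), W + off))
        ok <- all(sqrt((centers[seq_len(i - 1), 1] - ctr[1])^2 +
                       (centers[seq_len(i - 1), 2] - ctr[2])^2) >
                  rmax[i] + rmax[seq_len(i - 1)] + 2)
      }
      if (isTRUE(ok)) {
        centers[i, ] <- ctr
        blobs[[i]] <- make_star_convex_blob(ctr, radii[i], cfg$irregularity,
                                            blob_seeds[i], c(H, W))
        if (sum(blobs[[i]]) < 5) next
        placed <- TRUE
        break
      }
    }
    if (!placed) place_fail(role)
  }

  # paint: later nucleus wins contested pixels
  mask <- matrix(0L, H, W)
  for (i in seq_len(n)) mask[blobs[[i]]] <- i
  if (n > 0 && !all(seq_len(n) %in% mask))
    stop("scene placement failed: a nucleus was fully occluded during painting")

  # pre-resolution overlap flags
  overlaps <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dc <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (dc <= rmax[i] + rmax[j] && any(blobs[[i]] & blobs[[j]])) {
        overlaps[i] <- TRUE; overlaps[j] <- TRUE
      }
    }
  }
  touches <- vapply(seq_len(n), function(i) {
    px <- which(mask == i, arr.ind = TRUE)
    any(px[, 1] == 1 | px[, 1] == H | px[, 2] == 1 | px[, 2] == W)
  }, logical(1))

  # dot signals inside final nucleus pixels
  reds <- if (n > 0) sample(cfg$red_signal_range[1]:cfg$red_signal_range[2],
                            n, replace = TRUE) else integer(0)
  blacks <- if (n > 0) sample(cfg$black_signal_range[1]:cfg$black_signal_range[2],
                              n, replace = TRUE) else integer(0)
  dot_px <- function(i, k) {
    if (k == 0) return(matrix(numeric(0), 0, 2))
    px <- which(mask == i, arr.ind = TRUE)
    inner <- px[px[, 1] > 2 & px[, 1] < H - 1 & px[, 2] > 2 & px[, 2] < W - 1, ,
                drop = FALSE]
    if (nrow(inner) == 0) inner <- px
    inner[sample.int(nrow(inner), k, replace = nrow(inner) < k), , drop = FALSE]
  }
  red_pos <- lapply(seq_len(n), function(i) dot_px(i, reds[i]))
  black_pos <- lapply(seq_len(n), function(i) dot_px(i, blacks[i]))

  # concentration maps
  bg_conc <- -log10(cfg$background_intensity / 255) / mean(cfg$stain_matrix[, 1])
  conc1 <- matrix(bg_conc, H, W)
  conc2 <- matrix(0, H, W)
  levels <- runif(max(n, 1), 0.55, 0.95)
  for (i in seq_len(n)) conc1[mask == i] <- levels[i]
  paint_dot <- function(conc, pos, value) {
    for (r in seq_len(nrow(pos))) {
      rr <- pos[r, 1] + (-1:1); cc <- pos[r, 2] + (-1:1)
      sel <- expand.grid(rr = rr[rr >= 1 & rr <= H], cc = cc[cc >= 1 & cc <= W])
      keep <- abs(sel$rr - pos[r, 1]) + abs(sel$cc - pos[r, 2]) <= 1
      conc[cbind(sel$rr[keep], sel$cc[keep])] <- value
    }
    conc
  }
  for (i in seq_len(n)) {
    if (nrow(red_pos[[i]]) > 0) {
      conc2 <- paint_dot(conc2, red_pos[[i]], runif(1, 0.9, 1.2))
      conc1 <- paint_dot(conc1, red_pos[[i]], bg_conc)
    }
    if (nrow(black_pos[[i]]) > 0) {
      # both stains heavy: a dark, in-span silver signal that stays
      # within the 0-255 dynamic range
      conc1 <- paint_dot(conc1, black_pos[[i]], 1.1)
      conc2 <- paint_dot(conc2, black_pos[[i]], 1.1)
    }
  }

  nuclei <- nuclei_table(mask, n, reds, blacks, touches, overlaps)
  scene <- structure(list(image = NULL, mask = mask, nuclei = nuclei,
                          conc1 = conc1, conc2 = conc2, config = cfg),
                     class = "sish_scene")
  scene$image <- render_scene(scene, cfg$stain_matrix, cfg$noise_sd)
  stopifnot(identical(nrow(nuclei), n))
  scene
}

nuclei_table <- function(mask, n, reds, blacks, touches, overlaps) {
  if (n == 0)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), red_signals = integer(0),
                      black_signals = integer(0), touches_border = logical(0),
                      overlaps_neighbor = logical(0)))
  rows <- cols <- areas <- numeric(n)
  for (i in seq_len(n)) {
    px <- which(mask == i, arr.ind = TRUE)
    rows[i] <- mean(px[, 1]); cols[i] <- mean(px[, 2]); areas[i] <- nrow(px)
  }
  data.frame(label = seq_len(n), row = rows, col = cols,
             area = as.integer(areas), red_signals = as.integer(reds),
             black_signals = as.integer(blacks), touches_border = touches,
             overlaps_neighbor = overlaps)
}

#' Render a scene's stain concentration maps to an RGB image
#'
#' Applies the inverse optical-density transform `I = 255 * 10^(-M c)` to
#' the scene's two concentration maps, adds Gaussian intensity noise, and
#' clips to 0-255. Re-rendering the same scene through a different stain
#' basis yields a stain-shifted twin with identical geometry, which is how
#' normalization is validated.
#'
#' @param scene A `sish_scene`.
#' @param stain_matrix 3x2 unit-column stain basis to render through.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param noise_seed Seed for the noise draw (ignored when `noise_sd = 0`).
#' @param conc_scale Length-1 or length-2 concentration multiplier
#'   emulating per-stain staining strength variation between slides
#'   (default 1).
#' @return H x W x 3 integer array in 0-255.
#' @export
render_scene <- function(scene, stain_matrix = scene$config$stain_matrix,
                         noise_sd = scene$config$noise_sd,
                         noise_seed = scene$config$seed + 1L,
                         conc_scale = 1) {
  H <- nrow(scene$conc1); W <- ncol(scene$conc1)
  conc <- rep(conc_scale, length.out = 2) *
    rbind(as.vector(scene$conc1), as.vector(scene$conc2))
  od <- stain_matrix %*% conc # 3 x (H*W)
  img <- 255 * 10^(-od)
  if (noise_sd > 0)
    img <- img + withr::with_seed(as.integer(noise_seed),
                                  matrix(rnorm(length(img), 0, noise_sd),
                                         nrow(img)))
  img <- pmin(pmax(round(img), 0), 255)
  out <- array(0L, c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- as.integer(img[ch, ])
  out
}
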