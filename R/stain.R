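#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform `OD = -log10(I / i0)` per channel,
#' the space in which stain contributions combine linearly. Intensities
#' are clamped to `[1, i0]` before the logarithm, so the result is finite
#' and non-negative, and a pixel at the white point `i0` maps to OD 0.
#'
#' @param image H x W x 3 numeric/integer array with values in 0-255.
#' @param i0 White-point intensity (default 255).
#' @return H x W x 3 optical-density array with attribute `i0`.
#' @export
rgb_to_od <- function(image, i0 = 255) {
  if (i0 <= 0) stop("i0 must be positive")
  od <- -log10(pmin(pmax(image, 1), i0) / i0)
  attr(od, "i0") <- i0
  od
}

#' Convert optical density back to RGB
#'
#' Inverse of [rgb_to_od()]: `I = i0 * 10^(-OD)`, rounded and clipped to
#' 0-255.
#'
#' @param od H x W x 3 optical-density array.
#' @param i0 White-point intensity; defaults to the `i0` attribute of
#'   `od`, else 255.
#' @return Integer array of the same shape with values in 0-255.
#' @export
od_to_rgb <- function(od, i0 = NULL) {
  if (is.null(i0)) i0 <- attr(od, "i0") %||% 255
  img <- round(i0 * 10^(-od))
  storage.mode(img) <- "integer"
  img[] <- pmin(pmax(img, 0L), 255L)
  attr(img, "i0") <- NULL
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate a two-stain profile by the Macenko method
#'
#' Keeps tissue pixels (every channel's OD at least `beta`), projects
#' them onto the plane of the top two singular vectors of the OD cloud,
#' and takes the `alpha` and `100 - alpha` percentile angles in that
#' plane as the two stain directions. Stain vectors are returned with
#' non-negative orientation; the column with the larger red-channel OD
#' component is stain 1. Robust per-stain maximum concentrations are the
#' 99th percentiles of the least-squares unmixing of all image pixels.
#'
#' @param od OD image from [rgb_to_od()] (or any H x W x 3 OD array).
#' @param alpha Angular percentile in (0, 50); default 1.
#' @param beta OD transparency threshold; default 0.15.
#' @return An object of class `stain_profile`: list with `vectors`
#'   (3 x 2, unit columns), `max_concentrations` (length 2), `alpha`,
#'   `beta`.
#' @export
estimate_stain_profile <- function(od, alpha = 1, beta = 0.15) {
  if (alpha <= 0 || alpha >= 50) stop("alpha must lie in (0, 50)")
  if (beta <= 0) stop("beta must be positive")
  X <- matrix(od, ncol = 3)
  tissue <- X[X[, 1] >= beta & X[, 2] >= beta & X[, 3] >= beta, , drop = FALSE]
  if (nrow(tissue) < 100)
    stop("too few tissue pixels above the OD threshold to estimate stains")
  sv <- svd(tissue, nu = 0, nv = 2)
  V <- sv$v
  # deterministic basis orientation: largest-magnitude component positive
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  proj <- tissue %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE, type = 7)
  mk <- function(a) {
    v <- V[, 1] * cos(a) + V[, 2] * sin(a)
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- mk(qs[1]); v2 <- mk(qs[2])
  M <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  dimnames(M) <- NULL
  # robust maxima over tissue pixels only: the pale background would
  # otherwise dominate the percentile and make it content-dependent
  conc <- unmix_concentrations(tissue, M)
  prof <- list(vectors = M,
               max_concentrations = apply(conc, 1, quantile, probs = 0.99,
                                          names = FALSE),
               alpha = alpha, beta = beta)
  class(prof) <- "stain_profile"
  prof
}

# OLS unmixing of OD pixels (n x 3) against a 3 x 2 stain basis,
# concentrations clipped at zero. Returns 2 x n.
unmix_concentrations <- function(X, M) {
  sol <- tryCatch(solve(crossprod(M), t(M) %*% t(X)),
                  error = function(e) stop("singular stain unmixing system"))
  pmax(sol, 0)
}

validate_stain_profile <- function(p) {
  stopifnot(inherits(p, "stain_profile") || is.list(p))
  if (any(abs(sqrt(colSums(p$vectors^2)) - 1) > 1e-6))
    stop("stain profile columns must be unit norm")
  if (any(p$max_concentrations <= 0))
    stop("stain profile max_concentrations must be positive")
  invisible(p)
}

#' Normalize an image to a reference stain appearance
#'
#' Unmixes the image into two stain concentration maps against the
#' source profile (ordinary least squares in OD space, zero-clipped),
#' rescales each map by the ratio of reference to source robust maximum
#' concentrations, and recomposes through the reference stain vectors
#' and the inverse OD transform.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param source `stain_profile` of the image itself (estimated if
#'   `NULL`).
#' @param reference Target `stain_profile`.
#' @param i0 White-point intensity.
#' @return Normalized H x W x 3 integer RGB array.
#' @export
normalize_to_reference <- function(image, source = NULL, reference,
                                   i0 = 255) {
  od <- rgb_to_od(image, i0)
  if (is.null(source)) source <- estimate_stain_profile(od)
  validate_stain_profile(source); validate_stain_profile(reference)
  X <- matrix(od, ncol = 3)
  conc <- unmix_concentrations(X, source$vectors)
  conc <- conc * (reference$max_concentrations / source$max_concentrations)
  od2 <- t(reference$vectors %*% conc)
  out <- od_to_rgb(array(od2, dim(image)), i0)
  out
}

#' Angular distance between stain vectors
#'
#' @param u,v Numeric vectors.
#' @return Angle in degrees between the directions of `u` and `v`
#'   (orientation-insensitive).
#' @export
stain_angle <- function(u, v) {
  cs <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over all fully interior positions of a square uniform
#' window, with the standard stabilizers `C1 = (0.01 L)^2` and
#' `C2 = (0.03 L)^2`.
#'
#' @param a,b Grayscale matrices of identical shape.
#' @param L Dynamic range (default 255).
#' @param window Odd window side length (default 7).
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(a, b, L = 255, window = 7) {
  if (!all(dim(a) == dim(b))) stop("ssim inputs must have the same shape")
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (any(dim(a) < window)) stop("image smaller than the SSIM window")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  a <- matrix(as.numeric(a), nrow(a)); b <- matrix(as.numeric(b), nrow(b))
  mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
  saa <- box_mean(a * a, window) - mu_a^2
  sbb <- box_mean(b * b, window) - mu_b^2
  sab <- box_mean(a * b, window) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  mean(s)
}

# Uniform box-filter means over all fully interior window positions,
# computed with an integral image.
box_mean <- function(x, window) {
  h <- window %/% 2
  H <- nrow(x); W <- ncol(x)
  ii <- matrix(0, H + 1, W + 1)
  ii[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  r1 <- (1 + h):(H - h); c1 <- (1 + h):(W - h)
  lo_r <- r1 - h; hi_r <- r1 + h; lo_c <- c1 - h; hi_c <- c1 + h
  (ii[hi_r + 1, hi_c + 1] - ii[lo_r, hi_c + 1] -
   ii[hi_r + 1, lo_c] + ii[lo_r, lo_c]) / window^2
}

#' Convert an RGB array to luminance
#'
#' Rec. 601 luminance `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image H x W x 3 array.
#' @return H x W numeric matrix.
#' @export
rgb_to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

ref_profile_cache <- new.env(parent = emptyenv())

#' The package's reference stain profile
#'
#' A fixed stain profile serving as the normalization target. It is
#' estimated from a canonical noise-free synthetic SISH reference scene
#' (seed 42, default stain basis) and shipped as a JSON constant under
#' `inst/extdata/`; the scene itself is synthetic, not derived from any
#' clinical image.
#'
#' @return A `stain_profile`.
#' @export
reference_stain_profile <- function() {
  if (!is.null(ref_profile_cache$profile)) return(ref_profile_cache$profile)
  path <- system.file("extdata", "reference_stain_profile.json",
                      package = "sishdetect")
  prof <- read_stain_profile(path)
  ref_profile_cache$profile <- prof
  prof
}

#' Read / write a stain profile as JSON
#'
#' @param path File path.
#' @param profile A `stain_profile`.
#' @return `read_stain_profile` returns a `stain_profile`;
#'   `write_stain_profile` returns `path` invisibly.
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- list(vectors = matrix(x$vectors, 3, 2, byrow = TRUE),
               max_concentrations = x$max_concentrations,
               alpha = x$alpha, beta = x$beta)
  class(prof) <- "stain_profile"
  validate_stain_profile(prof)
}

#' @rdname read_stain_profile
#' @export
write_stain_profile <- function(profile, path) {
  validate_stain_profile(profile)
  jsonlite::write_json(list(vectors = as.vector(t(profile$vectors)),
                            max_concentrations = profile$max_concentrations,
                            alpha = profile$alpha, beta = profile$beta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
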