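#' Contrast-enhanced grayscale conversion
#'
#' Converts an RGB image to Rec. 601 luminance and stretches it by
#' histogram equalization to the full 0-255 range (CDF mapping with the
#' minimum occupied bin anchored at 0). A single-valued image is
#' returned unchanged: equalizing one bin is a no-op.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @return H x W numeric matrix of equalized luminance in 0-255.
#' @export
enhance_contrast <- function(image) {
  if (length(image) == 0) stop("empty image")
  gray <- round(rgb_to_gray(image))
  v <- as.integer(gray)
  if (length(unique(v)) < 2) return(gray)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  map <- round(255 * (cdf - cdf_min) / (length(v) - cdf_min))
  matrix(map[v + 1L], nrow(gray), ncol(gray))
}

#' Foreground mask by combined global and local thresholding
#'
#' Nuclei are darker than the background, so foreground pixels are those
#' below the global Otsu threshold or below a local mean threshold minus
#' a fixed offset. The raw mask is cleaned by a morphological opening
#' with a disk and by filling interior holes smaller than `min_hole`.
#'
#' @param gray H x W grayscale matrix (0-255), typically from
#'   [enhance_contrast()].
#' @param local_block Odd side length of the local-mean window (px).
#' @param min_hole Holes smaller than this many pixels are filled.
#' @param open_radius Disk radius of the morphological opening (px).
#' @param local_offset Intensity offset subtracted from the local mean.
#' @return H x W logical matrix, `TRUE` on nuclei/tissue foreground.
#' @export
compute_foreground_mask <- function(gray, local_block = 51, min_hole = 20,
                                    open_radius = 2, local_offset = 10) {
  if (local_block %% 2 != 1 || local_block < 3)
    stop("local_block must be odd and >= 3")
  if (length(unique(as.vector(gray))) < 2)
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  thr <- EBImage::otsu(EBImage::Image(gray / 255), range = c(0, 1)) * 255
  local_mean <- box_mean_padded(gray, local_block)
  mask <- (gray < thr) | (gray < local_mean - local_offset)
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2 * open_radius + 1, shape = "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(gray), ncol(gray))
  }
  fill_small_holes(mask, min_hole)
}

# Box mean with replicated borders (every output position defined).
box_mean_padded <- function(x, window) {
  h <- window %/% 2
  H <- nrow(x); W <- ncol(x)
  xp <- x[pmin(pmax(seq_len(H + 2 * h) - h, 1), H),
          pmin(pmax(seq_len(W + 2 * h) - h, 1), W)]
  box_mean(xp, window)
}

# Fill background components that do not touch the image border and are
# smaller than min_hole pixels.
fill_small_holes <- function(mask, min_hole) {
  if (min_hole <= 0 || !any(mask)) return(mask)
  comp <- .label8_cpp(!mask)
  H <- nrow(mask); W <- ncol(mask)
  border_labels <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  areas <- tabulate(comp)
  fill <- setdiff(which(areas < min_hole), border_labels)
  if (length(fill)) mask[comp %in% fill] <- TRUE
  mask
}

#' Remove small connected regions
#'
#' Connected components (8-connectivity) with area strictly below
#' `min_area` are set to background. For instance masks, surviving
#' labels keep their original ids.
#'
#' @param mask Logical matrix (binary mask) or integer matrix (instance
#'   mask, 0 = background).
#' @param min_area Minimum surviving component area in pixels.
#' @return Same type as `mask`.
#' @export
remove_small_regions <- function(mask, min_area) {
  if (min_area < 0) stop("min_area must be >= 0")
  if (min_area == 0 || !any(mask != 0)) return(mask)
  logical_in <- is.logical(mask)
  m <- mask
  storage.mode(m) <- "integer"
  comp <- .label8_int_cpp(m)
  areas <- tabulate(comp)
  small <- which(areas < min_area)
  if (length(small)) mask[comp %in% small] <- if (logical_in) FALSE else 0L
  mask
}
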