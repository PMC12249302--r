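#' Marker-controlled watershed baseline segmenter
#'
#' The conventional nuclei-detection baseline: Euclidean distance
#' transform of the foreground mask, markers at distance-map local
#' maxima with a minimum separation `h`, and marker-controlled region
#' growing on the negated distance map restricted to the foreground.
#'
#' @param image H x W x 3 RGB array (unused by the distance-based
#'   baseline itself; kept so any segmenter shares one signature).
#' @param foreground H x W logical foreground mask.
#' @param h Minimum marker separation in pixels (default 7).
#' @return H x W integer instance mask.
#' @export
watershed_baseline <- function(image, foreground, h = 7) {
  H <- nrow(foreground); W <- ncol(foreground)
  if (!any(foreground)) return(matrix(0L, H, W))
  d <- as.matrix(EBImage::distmap(EBImage::Image(foreground * 1),
                                  metric = "euclidean"))
  # local maxima within a (2h+1) box
  win <- 2 * h + 1
  dil <- as.matrix(EBImage::dilate(EBImage::Image(d),
                                   EBImage::makeBrush(win, shape = "box")))
  cand <- which(d > 0.5 & d >= dil - 1e-9, arr.ind = TRUE)
  if (nrow(cand) == 0) cand <- which(d == max(d), arr.ind = TRUE)[1, , drop = FALSE]
  ord <- order(-d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      dd <- sqrt((cand[later, 1] - cand[i, 1])^2 +
                 (cand[later, 2] - cand[i, 2])^2)
      keep[later[dd < h]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  seeds <- matrix(0L, H, W)
  seeds[cand] <- seq_len(nrow(cand))
  lab <- EBImage::propagate(EBImage::Image(max(d) - d),
                            EBImage::Image(seeds),
                            mask = EBImage::Image(foreground * 1),
                            lambda = 1e-4)
  out <- matrix(as.integer(round(as.matrix(lab))), H, W)
  out
}

#' Stage-1 pseudo-label generation
#'
#' Runs any instance segmenter, discards instances whose pixel majority
#' lies outside the foreground mask, removes small regions, and
#' relabels consecutively. This is the bootstrap that produces training
#' labels before any fine-tuned model exists; any segmenter with the
#' `(image, foreground)` signature plugs in.
#'
#' @param image H x W x 3 RGB array.
#' @param segmenter Function `(image, foreground) -> instance mask`
#'   (default: [watershed_baseline()]).
#' @param foreground H x W logical mask.
#' @param min_area Minimum surviving instance area (px^2).
#' @return H x W integer instance mask with consecutive labels.
#' @export
pseudo_label <- function(image, segmenter = watershed_baseline, foreground,
                         min_area = 30) {
  if (!any(foreground))
    return(matrix(0L, nrow(foreground), ncol(foreground)))
  mask <- segmenter(image, foreground)
  stopifnot(all(dim(mask) == dim(foreground)))
  labs <- setdiff(unique(as.vector(mask)), 0)
  for (lab in labs) {
    sel <- mask == lab
    if (mean(foreground[sel]) <= 0.5) mask[sel] <- 0L
  }
  mask <- remove_small_regions(mask, min_area)
  relabel_consecutive(mask)
}

#' Relabel an instance mask with consecutive ids starting at 1
#'
#' @param mask Integer instance mask.
#' @return Relabeled mask.
#' @export
relabel_consecutive <- function(mask) {
  labs <- sort(setdiff(unique(as.vector(mask)), 0))
  if (length(labs) == 0) return(mask)
  lut <- integer(max(labs)); lut[labs] <- seq_along(labs)
  mask[mask > 0] <- lut[mask[mask > 0]]
  mask
}

#' Divide an image/mask pair into training patches
#'
#' Grid crops of `patch_size` at the given stride, reflect-padding the
#' right/bottom edges so the grid covers the whole image. Patches whose
#' mask foreground fraction is below `min_foreground` are dropped;
#' instances clipped at patch borders keep their clipped shape.
#'
#' @param image H x W x 3 array.
#' @param mask H x W integer instance mask.
#' @param patch_size Square patch side (default 256).
#' @param stride Grid stride in pixels (default `patch_size`).
#' @param min_foreground Minimum mask foreground fraction to keep a
#'   patch.
#' @param source_id Identifier recorded with each patch.
#' @return List of patches, each a list with `image`, `mask`,
#'   `source_id`, `offset` (1-based row/col of the patch origin in the
#'   padded image).
#' @export
patchify <- function(image, mask, patch_size = 256, stride = patch_size,
                     min_foreground = 0, source_id = "image") {
  stopifnot(stride >= 1, all(dim(mask) == dim(image)[1:2]))
  H <- dim(image)[1]; W <- dim(image)[2]
  n_r <- max(1, ceiling((H - patch_size) / stride) + 1)
  n_c <- max(1, ceiling((W - patch_size) / stride) + 1)
  Hp <- (n_r - 1) * stride + patch_size
  Wp <- (n_c - 1) * stride + patch_size
  ri <- reflect_index(H, Hp); ci <- reflect_index(W, Wp)
  img_p <- image[ri, ci, , drop = FALSE]
  mask_p <- mask[ri, ci]
  out <- list()
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    r0 <- (i - 1) * stride + 1; c0 <- (j - 1) * stride + 1
    mp <- mask_p[r0:(r0 + patch_size - 1), c0:(c0 + patch_size - 1)]
    if (mean(mp > 0) < min_foreground) next
    out[[length(out) + 1]] <-
      list(image = img_p[r0:(r0 + patch_size - 1),
                         c0:(c0 + patch_size - 1), , drop = FALSE],
           mask = mp, source_id = source_id, offset = c(r0, c0))
  }
  out
}

# Index vector implementing edge reflection (without repeating the edge
# pixel) from length n to length target.
reflect_index <- function(n, target) {
  if (target <= n) return(seq_len(target))
  idx <- seq_len(n)
  while (length(idx) < target) {
    bounce <- rev(idx)[-1]
    idx <- c(idx, bounce[seq_len(min(length(bounce), target - length(idx)))])
  }
  idx
}

#' Seeded geometric augmentation of a patch
#'
#' Uniformly samples a rotation by a multiple of 90 degrees and
#' independent horizontal/vertical flips, applied identically to the
#' image and the mask. Restricting rotations to the square grid keeps
#' mask labels exact (no interpolation).
#'
#' @param patch List with `image` (H x W x C or H x W) and `mask`
#'   (H x W); patches must be square.
#' @param seed Integer seed; the same seed draws the same transform.
#' @return The transformed patch (other fields passed through).
#' @export
augment_patch <- function(patch, seed) {
  dm <- dim(patch$mask)
  if (dm[1] != dm[2]) stop("augmentation requires square patches")
  tr <- withr::with_seed(as.integer(seed),
                         list(k = sample(0:3, 1),
                              fh = runif(1) < 0.5, fv = runif(1) < 0.5))
  apply2d <- function(m) {
    for (i in seq_len(tr$k)) m <- t(m)[ncol(m):1, , drop = FALSE] # 90 deg CCW
    if (tr$fh) m <- m[, ncol(m):1, drop = FALSE]
    if (tr$fv) m <- m[nrow(m):1, , drop = FALSE]
    m
  }
  out <- patch
  out$mask <- apply2d(patch$mask)
  if (length(dim(patch$image)) == 3) {
    img <- array(patch$image[1], dim(patch$image)) # template
    for (ch in seq_len(dim(patch$image)[3]))
      img[, , ch] <- apply2d(patch$image[, , ch])
    out$image <- img
  } else {
    out$image <- apply2d(patch$image)
  }
  out
}
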