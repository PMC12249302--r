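#' Radial distance ground truth for an instance mask
#'
#' For every foreground pixel and each of `n_rays` rays at angles
#' `2*pi*k/n_rays` (direction `(sin, cos)` in row/col coordinates), the
#' ray is sampled in quarter-pixel steps from the pixel center, rounding
#' each sampled position to the nearest pixel; the distance is the last
#' sampled position before a pixel of a different label (or the image
#' edge) is hit. Background pixels are 0 on all rays.
#'
#' @param mask H x W integer instance mask (0 = background).
#' @param n_rays Number of rays (>= 8).
#' @return H x W x n_rays numeric array.
#' @export
compute_radial_distances <- function(mask, n_rays = 32) {
  if (n_rays < 8) stop("n_rays must be >= 8")
  m <- mask; storage.mode(m) <- "integer"
  .radial_distances_cpp(m, as.integer(n_rays))
}

#' Object probability ground truth
#'
#' Per-instance Euclidean distance to the instance boundary, normalized
#' by the instance's maximum, so each nucleus peaks at 1 near its center
#' and the background is exactly 0. Pixels near object centers thereby
#' dominate the distance loss and polygon candidate selection.
#'
#' @param mask H x W integer instance mask.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
compute_object_probability <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  prob <- matrix(0, H, W)
  labs <- setdiff(unique(as.vector(mask)), 0)
  for (lab in labs) {
    px <- which(mask == lab, arr.ind = TRUE)
    r0 <- max(1, min(px[, 1]) - 1); r1 <- min(H, max(px[, 1]) + 1)
    c0 <- max(1, min(px[, 2]) - 1); c1 <- min(W, max(px[, 2]) + 1)
    sub <- mask[r0:r1, c0:c1] == lab
    # pad so instance pixels at the image border are treated as boundary
    pad <- matrix(FALSE, nrow(sub) + 2, ncol(sub) + 2)
    pad[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
    d <- as.matrix(EBImage::distmap(EBImage::Image(pad * 1), metric = "euclidean"))
    d <- d[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)]
    mx <- max(d)
    if (mx > 0) {
      block <- prob[r0:r1, c0:c1]
      block[sub] <- d[sub] / mx
      prob[r0:r1, c0:c1] <- block
    }
  }
  prob
}

#' IoU of two star-convex polygon candidates
#'
#' Both polygons are rasterized on the integer pixel grid covering the
#' union of their bounding boxes; the value is the pixel-set
#' intersection over union. Two empty polygons have IoU 0 by
#' convention.
#'
#' @param a,b Polygon candidates: lists with `center` (row, col) and
#'   `radii` (length `n_rays`).
#' @return IoU in \[0, 1\].
#' @export
polygon_iou <- function(a, b) {
  if (length(a$radii) != length(b$radii))
    stop("candidates must share the ray count")
  .polygon_iou_cpp(as.numeric(a$center), as.numeric(a$radii),
                   as.numeric(b$center), as.numeric(b$radii))
}

#' Extract polygon candidates from predicted maps
#'
#' One candidate per pixel whose object probability exceeds
#' `prob_thresh`; the candidate's center is that pixel, its radii the
#' predicted radial distances there, and its score the pixel's
#' probability. Candidates are returned in deterministic row-major
#' (row fastest) order.
#'
#' @param prob H x W probability matrix.
#' @param dist H x W x n_rays distance array.
#' @param prob_thresh Probability threshold (default 0.5).
#' @return List with `centers` (n x 2 matrix, 1-based row/col), `radii`
#'   (n x n_rays matrix), `scores` (length n).
#' @export
candidate_polygons <- function(prob, dist, prob_thresh = 0.5) {
  stopifnot(all(dim(prob) == dim(dist)[1:2]))
  sel <- which(prob > prob_thresh) # column-major = row fastest within column
  n_rays <- dim(dist)[3]
  dmat <- matrix(dist, ncol = n_rays)
  list(centers = cbind(row(prob)[sel], col(prob)[sel]),
       radii = dmat[sel, , drop = FALSE],
       scores = as.numeric(prob[sel]))
}

#' Greedy non-maximum suppression of polygon candidates
#'
#' Candidates are processed by descending score (ties: smaller row,
#' then smaller column). A candidate is kept iff its IoU with every
#' already-kept candidate is below `iou_thresh`. The result is
#' therefore pairwise sub-threshold and independent of the input order.
#'
#' @param candidates As returned by [candidate_polygons()].
#' @param iou_thresh IoU threshold in (0, 1) (default 0.4).
#' @return The kept subset, in acceptance order, with a `kept_index`
#'   vector of 1-based indices into the input.
#' @export
greedy_nms <- function(candidates, iou_thresh = 0.4) {
  if (iou_thresh <= 0 || iou_thresh >= 1)
    stop("iou_thresh must lie strictly between 0 and 1")
  n <- length(candidates$scores)
  if (n == 0) return(c(candidates, list(kept_index = integer(0))))
  keep <- .greedy_nms_cpp(matrix(as.numeric(candidates$centers), n),
                          matrix(as.numeric(candidates$radii), n),
                          as.numeric(candidates$scores), iou_thresh)
  list(centers = candidates$centers[keep, , drop = FALSE],
       radii = candidates$radii[keep, , drop = FALSE],
       scores = candidates$scores[keep],
       kept_index = keep)
}

#' Rasterize kept polygons into a detection set
#'
#' Polygons are painted in ascending-score order so higher-score
#' polygons win contested pixels; empty instances (fully overpainted or
#' degenerate) are dropped and the rest renumbered consecutively.
#' Centroids are the mean painted pixel coordinates.
#'
#' @param kept Kept candidates from [greedy_nms()].
#' @param shape Length-2 integer (rows, cols) of the output mask.
#' @return An object of class `detection_set`: list with `polygons`
#'   (centers/radii/scores of surviving instances), `centroids` (n x 2),
#'   and `instance_mask`.
#' @export
rasterize_detections <- function(kept, shape) {
  n <- length(kept$scores)
  if (n == 0) {
    return(structure(list(polygons = list(centers = matrix(numeric(0), 0, 2),
                                          radii = matrix(numeric(0), 0, 0),
                                          scores = numeric(0)),
                          centroids = matrix(numeric(0), 0, 2),
                          instance_mask = matrix(0L, shape[1], shape[2])),
                     class = "detection_set"))
  }
  centers0 <- matrix(as.numeric(kept$centers), n) - 1 # to 0-based
  lab <- .paint_polygons_cpp(centers0, matrix(as.numeric(kept$radii), n),
                             as.numeric(kept$scores),
                             as.integer(shape[1]), as.integer(shape[2]))
  survivors <- sort(intersect(seq_len(n), unique(as.vector(lab))))
  relabel <- integer(n); relabel[survivors] <- seq_along(survivors)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  centroids <- t(vapply(seq_along(survivors), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }, numeric(2)))
  structure(list(polygons = list(centers = kept$centers[survivors, , drop = FALSE],
                                 radii = kept$radii[survivors, , drop = FALSE],
                                 scores = kept$scores[survivors]),
                 centroids = centroids,
                 instance_mask = lab),
            class = "detection_set")
}

#' Rasterize a single star-convex polygon
#'
#' @param center Length-2 (row, col), 1-based pixel coordinates.
#' @param radii Length `n_rays` distances.
#' @param shape Output (rows, cols).
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(center, radii, shape) {
  .rasterize_polygon_cpp(as.numeric(center) - 1, as.numeric(radii),
                         as.integer(shape[1]), as.integer(shape[2]))
}
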