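#' Match predicted and ground-truth instances
#'
#' Candidate pairs are those with IoU at or above `iou_thresh`; a
#' one-to-one assignment maximizing total IoU is then chosen (exact
#' search per connected component of the candidate graph). Matched
#' pairs are true positives; unmatched predictions are false positives
#' (so a nucleus split into k predictions yields 1 TP and k-1 FP) and
#' unmatched ground-truth objects are false negatives.
#'
#' @param pred,gt H x W integer instance masks of equal shape.
#' @param iou_thresh IoU threshold (default 0.5).
#' @return A `match_result`: list with `tp`, `fp`, `fn`, and `pairs`
#'   (matrix with columns `pred`, `gt`).
#' @export
match_instances <- function(pred, gt, iou_thresh = 0.5) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt must have the same shape")
  labs_p <- sort(setdiff(unique(as.vector(pred)), 0))
  labs_g <- sort(setdiff(unique(as.vector(gt)), 0))
  iou <- instance_iou_matrix(pred, gt)
  # rows/cols of iou are indexed by raw label value; restrict the
  # matching to labels actually present in each mask
  cand <- which(iou >= iou_thresh, arr.ind = TRUE)
  pairs <- max_weight_matching(cand, iou)
  tp <- nrow(pairs)
  res <- list(tp = tp, fp = length(labs_p) - tp, fn = length(labs_g) - tp,
              pairs = pairs)
  class(res) <- "match_result"
  res
}

# Pairwise IoU between labels of two masks via the label contingency
# table. Rows: pred labels 1..max, cols: gt labels 1..max (absent label
# ids give zero rows/columns).
instance_iou_matrix <- function(pred, gt) {
  n_pred <- max(0, max(pred)); n_gt <- max(0, max(gt))
  iou <- matrix(0, n_pred, n_gt)
  if (n_pred == 0 || n_gt == 0) return(iou)
  sel <- pred > 0 & gt > 0
  if (any(sel)) {
    key <- (as.numeric(pred[sel]) - 1) * n_gt + as.numeric(gt[sel])
    counts <- tabulate(key, nbins = n_pred * n_gt)
    inter <- matrix(counts, n_pred, n_gt, byrow = TRUE)
    area_p <- tabulate(pred[pred > 0], nbins = n_pred)
    area_g <- tabulate(gt[gt > 0], nbins = n_gt)
    uni <- outer(area_p, area_g, "+") - inter
    iou[uni > 0] <- inter[uni > 0] / uni[uni > 0]
  }
  iou
}

# Exact maximum-total-weight one-to-one matching on the candidate pairs
# (cand: matrix with pred/gt indices), solved independently per
# connected component by depth-first search.
max_weight_matching <- function(cand, iou) {
  if (nrow(cand) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("pred", "gt"))))
  # connected components over the bipartite candidate graph
  preds <- unique(cand[, 1])
  comp_of <- new.env(parent = emptyenv())
  adj_p <- split(cand[, 2], cand[, 1]) # gt lists per pred
  adj_g <- split(cand[, 1], cand[, 2])
  visited_p <- character(0)
  pairs <- NULL
  for (p0 in preds) {
    if (as.character(p0) %in% visited_p) next
    # BFS collect component
    comp_p <- integer(0); comp_g <- integer(0)
    queue_p <- p0; queue_g <- integer(0)
    while (length(queue_p) || length(queue_g)) {
      if (length(queue_p)) {
        p <- queue_p[1]; queue_p <- queue_p[-1]
        if (p %in% comp_p) next
        comp_p <- c(comp_p, p)
        queue_g <- c(queue_g, setdiff(adj_p[[as.character(p)]], comp_g))
      } else {
        g <- queue_g[1]; queue_g <- queue_g[-1]
        if (g %in% comp_g) next
        comp_g <- c(comp_g, g)
        queue_p <- c(queue_p, setdiff(adj_g[[as.character(g)]], comp_p))
      }
    }
    visited_p <- c(visited_p, as.character(comp_p))
    pairs <- rbind(pairs, component_matching(comp_p, comp_g, iou))
  }
  colnames(pairs) <- c("pred", "gt")
  pairs
}

component_matching <- function(comp_p, comp_g, iou) {
  best <- list(w = -1, assign = NULL)
  np <- length(comp_p)
  recurse <- function(i, used_g, w, assign) {
    if (i > np) {
      if (w > best$w + 1e-12 ||
          (abs(w - best$w) <= 1e-12 && sum(assign > 0) > sum(best$assign > 0))) {
        best <<- list(w = w, assign = assign)
      }
      return(invisible())
    }
    p <- comp_p[i]
    for (gi in seq_along(comp_g)) {
      g <- comp_g[gi]
      if (used_g[gi] || iou[p, g] <= 0) next
      assign[i] <- gi; used_g[gi] <- TRUE
      recurse(i + 1, used_g, w + iou[p, g], assign)
      assign[i] <- 0L; used_g[gi] <- FALSE
    }
    recurse(i + 1, used_g, w, assign) # leave p unmatched
  }
  recurse(1L, logical(length(comp_g)), 0, integer(np))
  sel <- which(best$assign > 0)
  cbind(comp_p[sel], comp_g[best$assign[sel]])
}

#' Match expert point annotations to detected instances
#'
#' A ground-truth point matches the predicted instance whose rasterized
#' region contains it; if several points fall in one instance, the one
#' nearest the instance centroid wins and the rest are false negatives.
#' Predictions containing no point count as false positives (restricted
#' to those overlapping `region`, when given). `tp + fn` equals the
#' number of points.
#'
#' @param detections A `detection_set` (or any list with
#'   `instance_mask` and `centroids`).
#' @param gt_points n x 2 matrix of (row, col) point annotations,
#'   1-based, within image bounds.
#' @param region Optional logical matrix restricting which unmatched
#'   predictions count as FP.
#' @return A `match_result` with `pairs` columns `pred`, `point`.
#' @export
match_points <- function(detections, gt_points, region = NULL) {
  inst <- detections$instance_mask
  centroids <- detections$centroids
  n_pts <- nrow(gt_points)
  labs_at <- if (n_pts > 0)
    inst[cbind(pmin(pmax(round(gt_points[, 1]), 1), nrow(inst)),
               pmin(pmax(round(gt_points[, 2]), 1), ncol(inst)))]
  else integer(0)
  pairs <- NULL
  fn <- 0L
  for (lab in setdiff(unique(labs_at), 0)) {
    pts <- which(labs_at == lab)
    if (length(pts) > 1) {
      d <- sqrt((gt_points[pts, 1] - centroids[lab, 1])^2 +
                (gt_points[pts, 2] - centroids[lab, 2])^2)
      win <- pts[which.min(d)]
      fn <- fn + length(pts) - 1L
    } else win <- pts
    pairs <- rbind(pairs, c(lab, win))
  }
  fn <- fn + sum(labs_at == 0)
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  matched_labs <- if (is.null(pairs)) integer(0) else pairs[, 1]
  all_labs <- setdiff(unique(as.vector(inst)), 0)
  unmatched <- setdiff(all_labs, matched_labs)
  if (!is.null(region) && length(unmatched))
    unmatched <- unmatched[vapply(unmatched, function(l)
      any(region[inst == l]), logical(1))]
  fp <- length(unmatched)
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("pred", "point")
  res <- list(tp = tp, fp = fp, fn = as.integer(fn), pairs = pairs)
  class(res) <- "match_result"
  res
}

#' Expert-criteria nucleus filter
#'
#' Keeps only nuclei suitable for HER2 quantification: at least two red
#' (CEN17) signals, non-overlapping, and non-border-touching.
#'
#' @param nuclei Data frame with columns `red_signals`,
#'   `overlaps_neighbor`, `touches_border` (as in a `sish_scene`).
#' @return The qualifying subset of rows.
#' @export
expert_filter <- function(nuclei) {
  need <- c("red_signals", "overlaps_neighbor", "touches_border")
  missing_cols <- setdiff(need, names(nuclei))
  if (length(missing_cols))
    stop("nuclei table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  nuclei[nuclei$red_signals >= 2 & !nuclei$overlaps_neighbor &
         !nuclei$touches_border, , drop = FALSE]
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Detection metrics from TP/FP/FN counts
#'
#' Recall `100*TP/(TP+FN)`, precision `100*TP/(TP+FP)` and F1
#' `100*2TP/(2TP+FN+FP)`, as percentages rounded half-up to one
#' decimal.
#'
#' @param counts A `match_result` or list with `tp`, `fp`, `fn`.
#' @param image_id Identifier for the evaluated image.
#' @return One-row data frame: `image_id`, `gt`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`, `f1`.
#' @export
detection_metrics <- function(counts, image_id = "image") {
  tp <- as.integer(counts$tp); fp <- as.integer(counts$fp)
  fn <- as.integer(counts$fn)
  if (tp + fp + fn == 0) stop("metrics undefined: tp = fp = fn = 0")
  recall <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn)) else NA_real_
  precision <- if (tp + fp > 0) round_half_up(100 * tp / (tp + fp)) else NA_real_
  f1 <- round_half_up(100 * 2 * tp / (2 * tp + fn + fp))
  data.frame(image_id = image_id, gt = tp + fn, tp = tp, fp = fp, fn = fn,
             recall = recall, precision = precision, f1 = f1,
             stringsAsFactors = FALSE)
}

#' Aggregate per-image metric rows into a report
#'
#' The mean (2 decimals) and sample standard deviation (1 decimal) of
#' the rounded per-image percentages, the same convention as the
#' benchmark count tables bundled with the package (standard rounding;
#' per-row metrics use half-up).
#'
#' @param rows Data frame of [detection_metrics()] rows.
#' @return An `evaluation_report`: list with `rows` and `summary` (mean
#'   and sd of recall, precision, f1).
#' @export
aggregate_report <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) stop("no metric rows to aggregate")
  s <- function(x) c(mean = round(mean(x), 2),
                     sd = round(if (length(x) > 1) sd(x) else 0, 1))
  summary <- data.frame(metric = c("recall", "precision", "f1"),
                        mean = c(s(rows$recall)[1], s(rows$precision)[1],
                                 s(rows$f1)[1]),
                        sd = c(s(rows$recall)[2], s(rows$precision)[2],
                               s(rows$f1)[2]))
  structure(list(rows = rows, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  cat("--\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare segmentation methods on an evaluation set
#'
#' Runs each named segmenter over the scenes, pools TP/FP/FN counts
#' against the ground-truth masks, and reports pooled precision,
#' recall and F1 per method.
#'
#' @param methods Named list of functions `scene -> instance mask`.
#' @param scenes List of `sish_scene` objects (ground truth is each
#'   scene's `mask`).
#' @param iou_thresh Match threshold (default 0.5).
#' @return Data frame with columns `method`, `precision`, `recall`,
#'   `f1` (percent, 1 decimal).
#' @export
compare_methods <- function(methods, scenes, iou_thresh = 0.5) {
  stopifnot(length(methods) >= 2, !is.null(names(methods)))
  out <- lapply(names(methods), function(nm) {
    tp <- fp <- fn <- 0L
    for (scene in scenes) {
      pred <- methods[[nm]](scene)
      m <- match_instances(pred, scene$mask, iou_thresh)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    data.frame(method = nm,
               precision = round_half_up(100 * tp / (tp + fp)),
               recall = round_half_up(100 * tp / (tp + fn)),
               f1 = round_half_up(100 * 2 * tp / (2 * tp + fn + fp)),
               tp = tp, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bundled benchmark detection-count tables
#'
#' Per-image TP/FP/FN count tables from a published HER2-SISH
#' nuclei-detection evaluation, bundled so the metric formulas can be
#' validated against an external worked example: `"visual"` counts all
#' objects resembling nuclei as ground truth; `"expert"` counts
#' expert-marked nuclei only.
#'
#' @param which `"visual"` or `"expert"`.
#' @return Data frame with columns `image_id`, `gt`, `tp`, `fp`, `fn`.
#' @export
sish_benchmark_counts <- function(which = c("visual", "expert")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("sish_benchmark_%s.csv", which),
                      package = "sishdetect")
  read.csv(path, colClasses = c(image_id = "character"))
}
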