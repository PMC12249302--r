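# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain R loops (no calls into the package's C++ kernels)
# so the fast implementations can be checked against them on small
# instances.

# Quarter-pixel ray marching, same stepping rule as the package.
oracle_radial_distances <- function(mask, n_rays) {
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0, c(H, W, n_rays))
  step <- 0.25
  for (r in seq_len(H)) for (c in seq_len(W)) {
    lab <- mask[r, c]
    if (lab == 0) next
    for (k in seq_len(n_rays)) {
      th <- 2 * pi * (k - 1) / n_rays
      drr <- sin(th); dcc <- cos(th)
      t <- step
      repeat {
        rr <- floor(r + t * drr + 0.5)
        cc <- floor(c + t * dcc + 0.5)
        if (rr < 1 || rr > H || cc < 1 || cc > W || mask[rr, cc] != lab) break
        t <- t + step
      }
      out[r, c, k] <- t - step
    }
  }
  out
}

# Star-polygon boundary distance at angle phi (independent R coding of
# the edge-intersection construction).
oracle_star_boundary <- function(radii, phi) {
  R <- length(radii); step <- 2 * pi / R
  p <- phi %% (2 * pi)
  k <- floor(p / step) %% R
  k2 <- (k + 1) %% R
  a <- radii[k + 1] * c(sin(k * step), cos(k * step))
  b <- radii[k2 + 1] * c(sin(k2 * step), cos(k2 * step))
  u <- c(sin(phi), cos(phi)); e <- b - a
  det <- u[2] * (-e[1]) - u[1] * (-e[2])
  if (abs(det) < 1e-12) return(min(radii[k + 1], radii[k2 + 1]))
  t <- (a[2] * (-e[1]) - a[1] * (-e[2])) / det
  max(t, 0)
}

oracle_in_polygon <- function(r, c, center, radii) {
  v <- c(r, c) - center
  rho <- sqrt(sum(v^2))
  if (rho < 1e-12) return(any(radii > 0))
  rho <= oracle_star_boundary(radii, atan2(v[1], v[2])) + 0.125
}

# Pixel-set IoU of two polygons over a grid covering both supports.
oracle_polygon_iou <- function(ca, ra, cb, rb) {
  rmax_a <- max(ra); rmax_b <- max(rb)
  rows <- floor(min(ca[1] - rmax_a, cb[1] - rmax_b) - 1):
          ceiling(max(ca[1] + rmax_a, cb[1] + rmax_b) + 1)
  cols <- floor(min(ca[2] - rmax_a, cb[2] - rmax_b) - 1):
          ceiling(max(ca[2] + rmax_a, cb[2] + rmax_b) + 1)
  inter <- 0; uni <- 0
  for (r in rows) for (c in cols) {
    ina <- oracle_in_polygon(r, c, ca, ra)
    inb <- oracle_in_polygon(r, c, cb, rb)
    if (ina && inb) inter <- inter + 1
    if (ina || inb) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

# Sequential greedy NMS using the oracle IoU.
oracle_nms <- function(centers, radii, scores, iou_thresh) {
  n <- length(scores)
  ord <- order(-scores, centers[, 1], centers[, 2])
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (oracle_polygon_iou(centers[i, ], radii[i, ],
                             centers[j, ], radii[j, ]) >= iou_thresh) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Exhaustive one-to-one assignment maximizing total IoU.
oracle_match <- function(pred, gt, iou_thresh) {
  labs_p <- setdiff(unique(as.vector(pred)), 0)
  labs_g <- setdiff(unique(as.vector(gt)), 0)
  iou <- matrix(0, length(labs_p), length(labs_g))
  for (i in seq_along(labs_p)) for (j in seq_along(labs_g)) {
    a <- pred == labs_p[i]; b <- gt == labs_g[j]
    u <- sum(a | b)
    iou[i, j] <- if (u > 0) sum(a & b) / u else 0
  }
  best <- list(w = -1, n = 0)
  recurse <- function(i, used, w, n) {
    if (i > length(labs_p)) {
      if (w > best$w + 1e-12 || (abs(w - best$w) <= 1e-12 && n > best$n))
        best <<- list(w = w, n = n)
      return(invisible())
    }
    for (j in seq_along(labs_g)) {
      if (!used[j] && iou[i, j] >= iou_thresh) {
        used[j] <- TRUE
        recurse(i + 1, used, w + iou[i, j], n + 1)
        used[j] <- FALSE
      }
    }
    recurse(i + 1, used, w, n)
  }
  recurse(1, logical(length(labs_g)), 0, 0)
  list(tp = best$n, fp = length(labs_p) - best$n, fn = length(labs_g) - best$n)
}

# Direct windowed SSIM (double loop over window positions).
oracle_ssim <- function(a, b, L = 255, window = 7) {
  h <- window %/% 2
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (r in (1 + h):(nrow(a) - h)) for (c in (1 + h):(ncol(a) - h)) {
    wa <- a[(r - h):(r + h), (c - h):(c + h)]
    wb <- b[(r - h):(r + h), (c - h):(c + h)]
    ma <- mean(wa); mb <- mean(wb)
    va <- mean(wa^2) - ma^2; vb <- mean(wb^2) - mb^2
    cab <- mean(wa * wb) - ma * mb
    vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                    ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# Small-region removal by flood fill (8-connectivity), per label value.
oracle_remove_small <- function(mask, min_area) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  out <- mask
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    val <- mask[r0, c0]
    comp <- matrix(c(r0, c0), 1)
    seen[r0, c0] <- TRUE
    frontier <- comp
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (dr in -1:1) for (dc in -1:1) {
          rr <- frontier[i, 1] + dr; cc <- frontier[i, 2] + dc
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
              !seen[rr, cc] && mask[rr, cc] == val) {
            seen[rr, cc] <- TRUE
            nxt <- rbind(nxt, c(rr, cc))
          }
        }
      }
      comp <- rbind(comp, nxt)
      frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
    if (nrow(comp) < min_area) out[comp] <- 0L
  }
  out
}

# A small random instance mask built from a few blobs.
random_blob_mask <- function(seed, H = 28, W = 28, n = 3) {
  withr::with_seed(seed, {
    mask <- matrix(0L, H, W)
    for (i in seq_len(n)) {
      ctr <- c(runif(1, 5, H - 4), runif(1, 5, W - 4))
      blob <- make_star_convex_blob(ctr, runif(1, 3.5, 6), runif(1, 0, 0.4),
                                    sample.int(1e6, 1), c(H, W))
      mask[blob] <- i
    }
    mask
  })
}
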