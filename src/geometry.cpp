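// Star-convex polygon geometry kernels: radial distance ground truth,
// polygon rasterization, IoU, greedy NMS, and 8-connected labeling.
// All pixel coordinates are 0-based (row, col) inside C++; R wrappers
// convert to/from 1-based indexing where needed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int round_half_up(double x) {
  return (int)std::floor(x + 0.5);
}

// Ray directions for n_rays rays: ray k points along angle 2*pi*k/n,
// with (drow, dcol) = (sin(a), cos(a)). Shared by every routine here and
// by the R-side polygon vertex construction.
static void ray_dirs(int n_rays, std::vector<double>& dr, std::vector<double>& dc) {
  dr.resize(n_rays); dc.resize(n_rays);
  for (int k = 0; k < n_rays; ++k) {
    double a = 2.0 * M_PI * k / n_rays;
    dr[k] = std::sin(a);
    dc[k] = std::cos(a);
  }
}

// [[Rcpp::export(name = ".radial_distances_cpp")]]
NumericVector radial_distances_cpp(IntegerMatrix mask, int n_rays) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<double> dr, dc;
  ray_dirs(n_rays, dr, dc);
  NumericVector out((R_xlen_t)H * W * n_rays);
  // quarter-pixel sampling along each ray: the distance is the last
  // sampled position whose nearest pixel still carries the same label,
  // so the exit point of the rasterized region is located to 0.25 px
  const double step = 0.25;
  int max_steps = 4 * (H + W + 2);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int lab = mask(r, c);
      if (lab == 0) continue;
      for (int k = 0; k < n_rays; ++k) {
        int t = 1;
        for (; t <= max_steps; ++t) {
          int rr = round_half_up(r + t * step * dr[k]);
          int cc = round_half_up(c + t * step * dc[k]);
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) break;
          if (mask(rr, cc) != lab) break;
        }
        out[(R_xlen_t)k * H * W + (R_xlen_t)c * H + r] = (t - 1) * step;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, n_rays);
  return out;
}

// Boundary distance of a star polygon (center at origin, vertex k at
// radius rad[k] along ray k) in direction angle phi. Intersects the ray
// with the edge between the two adjacent vertices.
static double star_boundary(const double* rad, int n_rays,
                            const std::vector<double>& dr,
                            const std::vector<double>& dc,
                            double phi) {
  double step = 2.0 * M_PI / n_rays;
  double p = phi;
  while (p < 0) p += 2.0 * M_PI;
  int k = (int)std::floor(p / step) % n_rays;
  int k2 = (k + 1) % n_rays;
  // edge endpoints
  double ar = rad[k] * dr[k],  ac = rad[k] * dc[k];
  double br = rad[k2] * dr[k2], bc = rad[k2] * dc[k2];
  double ur = std::sin(phi), uc = std::cos(phi);
  // solve A + s (B - A) = t u for t
  double er = br - ar, ec = bc - ac;
  double det = uc * (-er) - ur * (-ec); // [u, -(B-A)] columns
  if (std::fabs(det) < 1e-12) {
    // degenerate edge (both radii ~0 or collinear): fall back to nearer vertex
    return std::min(rad[k], rad[k2]);
  }
  double t = (ac * (-er) - ar * (-ec)) / det;
  return t > 0 ? t : 0.0;
}

static inline bool point_in_star(double prow, double pcol,
                                 double crow, double ccol,
                                 const double* rad, int n_rays,
                                 const std::vector<double>& dr,
                                 const std::vector<double>& dc) {
  double vr = prow - crow, vc = pcol - ccol;
  double rho = std::sqrt(vr * vr + vc * vc);
  if (rho < 1e-12) {
    // center itself: inside iff polygon has any extent
    for (int k = 0; k < n_rays; ++k) if (rad[k] > 0) return true;
    return false;
  }
  double phi = std::atan2(vr, vc);
  double b = star_boundary(rad, n_rays, dr, dc, phi);
  // coverage offset of half the ray sampling step (0.25 px): the radial
  // distance is the last inside sample, so the true region boundary lies
  // up to half a sample beyond it; this makes rasterization the inverse
  // of ray marching
  return rho <= b + 0.125;
}

// [[Rcpp::export(name = ".rasterize_polygon_cpp")]]
LogicalMatrix rasterize_polygon_cpp(NumericVector center, NumericVector radii,
                                    int nrow, int ncol) {
  int n_rays = radii.size();
  std::vector<double> dr, dc;
  ray_dirs(n_rays, dr, dc);
  LogicalMatrix out(nrow, ncol);
  double rmax = 0;
  for (int k = 0; k < n_rays; ++k) rmax = std::max(rmax, radii[k]);
  int r0 = std::max(0, (int)std::floor(center[0] - rmax - 0.5));
  int r1 = std::min(nrow - 1, (int)std::ceil(center[0] + rmax + 0.5));
  int c0 = std::max(0, (int)std::floor(center[1] - rmax - 0.5));
  int c1 = std::min(ncol - 1, (int)std::ceil(center[1] + rmax + 0.5));
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r)
      out(r, c) = point_in_star(r, c, center[0], center[1],
                                radii.begin(), n_rays, dr, dc);
  return out;
}

static double poly_iou_impl(double ar0, double ac0, const double* rada,
                            double br0, double bc0, const double* radb,
                            int n_rays,
                            const std::vector<double>& dr,
                            const std::vector<double>& dc) {
  double rmax_a = 0, rmax_b = 0;
  for (int k = 0; k < n_rays; ++k) {
    rmax_a = std::max(rmax_a, rada[k]);
    rmax_b = std::max(rmax_b, radb[k]);
  }
  double dcent = std::hypot(ar0 - br0, ac0 - bc0);
  if (dcent > rmax_a + rmax_b + 1.5) return 0.0;
  int r0 = (int)std::floor(std::min(ar0 - rmax_a, br0 - rmax_b) - 0.5);
  int r1 = (int)std::ceil(std::max(ar0 + rmax_a, br0 + rmax_b) + 0.5);
  int c0 = (int)std::floor(std::min(ac0 - rmax_a, bc0 - rmax_b) - 0.5);
  int c1 = (int)std::ceil(std::max(ac0 + rmax_a, bc0 + rmax_b) + 0.5);
  long inter = 0, uni = 0;
  for (int r = r0; r <= r1; ++r) {
    for (int c = c0; c <= c1; ++c) {
      bool ina = point_in_star(r, c, ar0, ac0, rada, n_rays, dr, dc);
      bool inb = point_in_star(r, c, br0, bc0, radb, n_rays, dr, dc);
      if (ina && inb) ++inter;
      if (ina || inb) ++uni;
    }
  }
  if (uni == 0) return 0.0; // both empty after rasterization
  return (double)inter / (double)uni;
}

// [[Rcpp::export(name = ".polygon_iou_cpp")]]
double polygon_iou_cpp(NumericVector center_a, NumericVector radii_a,
                       NumericVector center_b, NumericVector radii_b) {
  int n_rays = radii_a.size();
  std::vector<double> dr, dc;
  ray_dirs(n_rays, dr, dc);
  return poly_iou_impl(center_a[0], center_a[1], radii_a.begin(),
                       center_b[0], center_b[1], radii_b.begin(),
                       n_rays, dr, dc);
}

// Greedy NMS. centers: n x 2, radii: n x R, scores: n.
// Candidates are processed by descending score, ties broken by smaller
// row then smaller col; a candidate is kept iff its IoU with every
// already-kept candidate is < iou_thresh. Returns 1-based indices into
// the input, in acceptance order.
// [[Rcpp::export(name = ".greedy_nms_cpp")]]
IntegerVector greedy_nms_cpp(NumericMatrix centers, NumericMatrix radii,
                             NumericVector scores, double iou_thresh) {
  int n = centers.nrow();
  int n_rays = radii.ncol();
  std::vector<double> dr, dc;
  ray_dirs(n_rays, dr, dc);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (scores[a] != scores[b]) return scores[a] > scores[b];
    if (centers(a, 0) != centers(b, 0)) return centers(a, 0) < centers(b, 0);
    return centers(a, 1) < centers(b, 1);
  });
  // row-major copies of radii for cache friendliness
  std::vector<std::vector<double>> rad(n, std::vector<double>(n_rays));
  std::vector<double> rmax(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_rays; ++k) {
      rad[i][k] = radii(i, k);
      rmax[i] = std::max(rmax[i], rad[i][k]);
    }
  std::vector<int> kept;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    bool ok = true;
    for (size_t j = 0; j < kept.size(); ++j) {
      int kj = kept[j];
      double dcent = std::hypot(centers(i, 0) - centers(kj, 0),
                                centers(i, 1) - centers(kj, 1));
      if (dcent > rmax[i] + rmax[kj] + 1.5) continue;
      double iou = poly_iou_impl(centers(i, 0), centers(i, 1), rad[i].data(),
                                 centers(kj, 0), centers(kj, 1), rad[kj].data(),
                                 n_rays, dr, dc);
      if (iou >= iou_thresh) { ok = false; break; }
    }
    if (ok) kept.push_back(i);
  }
  IntegerVector out(kept.size());
  for (size_t j = 0; j < kept.size(); ++j) out[j] = kept[j] + 1;
  return out;
}

// Paint kept polygons into a label image. Polygons are painted in
// ascending-score order so that higher-score polygons overwrite
// contested pixels. labels follow the input order (1..n).
// [[Rcpp::export(name = ".paint_polygons_cpp")]]
IntegerMatrix paint_polygons_cpp(NumericMatrix centers, NumericMatrix radii,
                                 NumericVector scores, int nrow, int ncol) {
  int n = centers.nrow();
  int n_rays = radii.ncol();
  std::vector<double> dr, dc;
  ray_dirs(n_rays, dr, dc);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  // ascending score; ties painted in reverse input order so that the
  // earlier (higher-priority) candidate is painted last and wins
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (scores[a] != scores[b]) return scores[a] < scores[b];
    return a > b;
  });
  IntegerMatrix out(nrow, ncol);
  std::vector<double> radv(n_rays);
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    double rmax = 0;
    for (int k = 0; k < n_rays; ++k) { radv[k] = radii(i, k); rmax = std::max(rmax, radv[k]); }
    int r0 = std::max(0, (int)std::floor(centers(i, 0) - rmax - 0.5));
    int r1 = std::min(nrow - 1, (int)std::ceil(centers(i, 0) + rmax + 0.5));
    int c0 = std::max(0, (int)std::floor(centers(i, 1) - rmax - 0.5));
    int c1 = std::min(ncol - 1, (int)std::ceil(centers(i, 1) + rmax + 0.5));
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (point_in_star(r, c, centers(i, 0), centers(i, 1),
                          radv.data(), n_rays, dr, dc))
          out(r, c) = i + 1;
  }
  return out;
}

// 8-connected labeling of same-valued nonzero regions of an integer
// matrix: two pixels join a component iff they are 8-adjacent and carry
// the same nonzero value. For a 0/1 matrix this is plain binary labeling.
// [[Rcpp::export(name = ".label8_int_cpp")]]
IntegerMatrix label8_int_cpp(IntegerMatrix x) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!x(r, c) || lab(r, c)) continue;
      int val = x(r, c);
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto pc = stack.back(); stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int rr = pc.first + dr8[k], cc = pc.second + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (x(rr, cc) == val && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// 8-connected labeling of a logical/integer matrix (nonzero = foreground).
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix x) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!x(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto pc = stack.back(); stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int rr = pc.first + dr8[k], cc = pc.second + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (x(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}
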