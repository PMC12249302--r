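// Compact U-Net engine: forward pass, loss, and manual backpropagation.
// The network maps an H x W x Cin image to a per-pixel object probability
// (sigmoid head) and n_rays radial boundary distances (softplus head).
// Convolutions are 3x3 same-padding implemented via im2col + BLAS matmul;
// heads are 1x1. Downsampling is 2x2 max-pool, upsampling nearest-neighbour,
// with channel concatenation skip connections.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

struct LayerSpec { int kin, kout, ksize; };

// Layer order: encoder (2 convs per level), bottleneck (2), decoder
// (2 per level, first one takes the concatenated channels), then the
// probability head and the distance head (both 1x1).
static std::vector<LayerSpec> layer_spec(int depth, int nf, int nrays, int inch) {
  std::vector<LayerSpec> L;
  int cin = inch;
  for (int d = 0; d < depth; ++d) {
    int cout = nf << d;
    L.push_back({cin, cout, 3});
    L.push_back({cout, cout, 3});
    cin = cout;
  }
  int cb = nf << depth;
  L.push_back({cin, cb, 3});
  L.push_back({cb, cb, 3});
  cin = cb;
  for (int d = depth - 1; d >= 0; --d) {
    int cout = nf << d;
    L.push_back({cin + cout, cout, 3}); // after upsample + concat skip
    L.push_back({cout, cout, 3});
    cin = cout;
  }
  L.push_back({cin, 1, 1});     // probability logits
  L.push_back({cin, nrays, 1}); // distance pre-activations
  return L;
}

// [[Rcpp::export(name = ".unet_layer_spec")]]
IntegerMatrix unet_layer_spec(int depth, int nf, int nrays, int inch) {
  auto L = layer_spec(depth, nf, nrays, inch);
  IntegerMatrix out(L.size(), 3);
  for (size_t i = 0; i < L.size(); ++i) {
    out(i, 0) = L[i].kin; out(i, 1) = L[i].kout; out(i, 2) = L[i].ksize;
  }
  return out;
}

struct Layer { mat W; vec b; };

static std::vector<Layer> unflatten(const NumericVector& p,
                                    const std::vector<LayerSpec>& spec) {
  std::vector<Layer> layers(spec.size());
  R_xlen_t off = 0;
  for (size_t i = 0; i < spec.size(); ++i) {
    int rows = spec[i].ksize * spec[i].ksize * spec[i].kin;
    int cols = spec[i].kout;
    layers[i].W = mat(rows, cols);
    std::copy(p.begin() + off, p.begin() + off + (R_xlen_t)rows * cols,
              layers[i].W.memptr());
    off += (R_xlen_t)rows * cols;
    layers[i].b = vec(cols);
    std::copy(p.begin() + off, p.begin() + off + cols, layers[i].b.memptr());
    off += cols;
  }
  if (off != p.size()) stop("parameter vector length does not match architecture");
  return layers;
}

// im2col for 3x3 same-padding convolution: X is (H*W) x (9*Cin) with
// column index q = ci*9 + (dy+1)*3 + (dx+1); pixel rows are col-major.
static mat im2col3(const cube& in) {
  int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat X((R_xlen_t)H * W, 9 * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& sl = in.slice(ci);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int q = ci * 9 + (dy + 1) * 3 + (dx + 1);
        double* xcol = X.colptr(q);
        for (int c = 0; c < W; ++c) {
          int cs = c + dx;
          if (cs < 0 || cs >= W) continue;
          int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
          const double* src = sl.colptr(cs);
          double* dst = xcol + (R_xlen_t)c * H;
          for (int r = r0; r <= r1; ++r) dst[r] = src[r + dy];
        }
      }
    }
  }
  return X;
}

static void col2im3(const mat& dX, cube& din) {
  int H = din.n_rows, W = din.n_cols, C = din.n_slices;
  din.zeros();
  for (int ci = 0; ci < C; ++ci) {
    mat& sl = din.slice(ci);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int q = ci * 9 + (dy + 1) * 3 + (dx + 1);
        const double* xcol = dX.colptr(q);
        for (int c = 0; c < W; ++c) {
          int cs = c + dx;
          if (cs < 0 || cs >= W) continue;
          int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
          double* dst = sl.colptr(cs);
          const double* src = xcol + (R_xlen_t)c * H;
          for (int r = r0; r <= r1; ++r) dst[r + dy] += src[r];
        }
      }
    }
  }
}

static cube mat_to_cube(const mat& Y, int H, int W) {
  cube out(H, W, Y.n_cols);
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.memptr());
  return out;
}

static mat cube_to_mat(const cube& x) {
  mat out((R_xlen_t)x.n_rows * x.n_cols, x.n_slices);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.memptr());
  return out;
}

struct ConvCtx { cube in; cube out; }; // stored for backward

static cube conv_forward(const Layer& L, const cube& in, int ksize,
                         bool relu, ConvCtx& ctx) {
  int H = in.n_rows, W = in.n_cols;
  mat Y;
  if (ksize == 3) {
    mat X = im2col3(in);
    Y = X * L.W;
  } else {
    Y = cube_to_mat(in) * L.W;
  }
  Y.each_row() += L.b.t();
  if (relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
  ctx.in = in;
  cube out = mat_to_cube(Y, H, W);
  ctx.out = out;
  return out;
}

static cube conv_backward(const Layer& L, const ConvCtx& ctx, int ksize,
                          bool relu, const cube& dout,
                          mat& dW, vec& db) {
  int H = ctx.in.n_rows, W = ctx.in.n_cols;
  mat dY = cube_to_mat(dout);
  if (relu) {
    mat outm = cube_to_mat(ctx.out);
    dY %= arma::conv_to<mat>::from(outm > 0);
  }
  db = arma::sum(dY, 0).t();
  cube din(H, W, ctx.in.n_slices);
  if (ksize == 3) {
    mat X = im2col3(ctx.in);
    dW = X.t() * dY;
    mat dX = dY * L.W.t();
    col2im3(dX, din);
  } else {
    dW = cube_to_mat(ctx.in).t() * dY;
    mat dX = dY * L.W.t();
    din = mat_to_cube(dX, H, W);
  }
  return din;
}

static cube maxpool2(const cube& in, arma::ucube& argmax) {
  int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double best = in(2 * r, 2 * c, ci);
        unsigned which = 0;
        double v;
        v = in(2 * r + 1, 2 * c, ci);     if (v > best) { best = v; which = 1; }
        v = in(2 * r, 2 * c + 1, ci);     if (v > best) { best = v; which = 2; }
        v = in(2 * r + 1, 2 * c + 1, ci); if (v > best) { best = v; which = 3; }
        out(r, c, ci) = best;
        argmax(r, c, ci) = which;
      }
  return out;
}

static cube maxpool2_backward(const cube& dout, const arma::ucube& argmax,
                              int H, int W) {
  int C = dout.n_slices;
  cube din(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < (int)dout.n_cols; ++c)
      for (int r = 0; r < (int)dout.n_rows; ++r) {
        unsigned which = argmax(r, c, ci);
        din(2 * r + (which & 1), 2 * c + (which >> 1), ci) = dout(r, c, ci);
      }
  return din;
}

static cube upsample2(const cube& in) {
  int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = in(r, c, ci);
        out(2 * r, 2 * c, ci) = v;
        out(2 * r + 1, 2 * c, ci) = v;
        out(2 * r, 2 * c + 1, ci) = v;
        out(2 * r + 1, 2 * c + 1, ci) = v;
      }
  return out;
}

static cube upsample2_backward(const cube& dout) {
  int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  cube din(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        din(r, c, ci) = dout(2 * r, 2 * c, ci) + dout(2 * r + 1, 2 * c, ci) +
                        dout(2 * r, 2 * c + 1, ci) + dout(2 * r + 1, 2 * c + 1, ci);
  return din;
}

static inline double sigmoid(double z) {
  return z >= 0 ? 1.0 / (1.0 + std::exp(-z)) : std::exp(z) / (1.0 + std::exp(z));
}
static inline double softplus(double z) {
  if (z > 30) return z;
  if (z < -30) return std::exp(z);
  return std::log1p(std::exp(z));
}

// Runs the network on one image. If target_prob has length H*W, the
// composite loss (BCE on object probability + lambda * probability-weighted
// mean absolute error on radial distances) and, if want_grad, the full
// parameter gradient are also computed.
// [[Rcpp::export(name = ".unet_run")]]
List unet_run(NumericVector params, int depth, int nf, int nrays, int inch,
              NumericVector image, NumericVector target_prob,
              NumericVector target_dist, double lambda,
              bool binary_target, bool want_grad) {
  IntegerVector idim = image.attr("dim");
  int H = idim[0], W = idim[1];
  if (idim[2] != inch) stop("image channel count does not match architecture");
  if (H % (1 << depth) || W % (1 << depth))
    stop("image size must be a multiple of 2^depth");
  auto spec = layer_spec(depth, nf, nrays, inch);
  auto layers = unflatten(params, spec);

  cube x(H, W, inch);
  std::copy(image.begin(), image.end(), x.memptr());

  std::vector<ConvCtx> ctx(spec.size());
  std::vector<cube> skips(depth);
  std::vector<arma::ucube> argmaxes(depth);
  int li = 0;
  cube cur = x;
  for (int d = 0; d < depth; ++d) {
    cur = conv_forward(layers[li], cur, 3, true, ctx[li]); ++li;
    cur = conv_forward(layers[li], cur, 3, true, ctx[li]); ++li;
    skips[d] = cur;
    cur = maxpool2(cur, argmaxes[d]);
  }
  cur = conv_forward(layers[li], cur, 3, true, ctx[li]); ++li;
  cur = conv_forward(layers[li], cur, 3, true, ctx[li]); ++li;
  for (int d = depth - 1; d >= 0; --d) {
    cube up = upsample2(cur);
    cube cat(up.n_rows, up.n_cols, up.n_slices + skips[d].n_slices);
    cat.slices(0, up.n_slices - 1) = up;
    cat.slices(up.n_slices, cat.n_slices - 1) = skips[d];
    cur = conv_forward(layers[li], cat, 3, true, ctx[li]); ++li;
    cur = conv_forward(layers[li], cur, 3, true, ctx[li]); ++li;
  }
  int hp = li;      // prob head index
  int hd = li + 1;  // dist head index
  cube zp = conv_forward(layers[hp], cur, 1, false, ctx[hp]);
  cube zd = conv_forward(layers[hd], cur, 1, false, ctx[hd]);

  NumericVector prob((R_xlen_t)H * W);
  for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) prob[i] = sigmoid(zp.memptr()[i]);
  prob.attr("dim") = IntegerVector::create(H, W);
  NumericVector dist((R_xlen_t)H * W * nrays);
  for (R_xlen_t i = 0; i < (R_xlen_t)H * W * nrays; ++i)
    dist[i] = softplus(zd.memptr()[i]);
  dist.attr("dim") = IntegerVector::create(H, W, nrays);

  List out = List::create(_["prob"] = prob, _["dist"] = dist);
  if (target_prob.size() == 0) return out;
  if (target_prob.size() != (R_xlen_t)H * W ||
      target_dist.size() != (R_xlen_t)H * W * nrays)
    stop("target dimensions do not match image");

  R_xlen_t npix = (R_xlen_t)H * W;
  double bce = 0.0;
  cube dzp(H, W, 1, arma::fill::zeros);
  for (R_xlen_t i = 0; i < npix; ++i) {
    double z = zp.memptr()[i];
    double y = target_prob[i];
    if (binary_target) y = y > 0 ? 1.0 : 0.0;
    bce += std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::fabs(z)));
    dzp.memptr()[i] = (sigmoid(z) - y) / npix;
  }
  bce /= npix;

  double wsum = 0.0;
  for (R_xlen_t i = 0; i < npix; ++i) wsum += target_prob[i];
  double dl = 0.0;
  cube dzd(H, W, nrays, arma::fill::zeros);
  if (wsum > 0) {
    for (int k = 0; k < nrays; ++k) {
      const double* dv = dist.begin() + (R_xlen_t)k * npix;
      const double* tv = target_dist.begin() + (R_xlen_t)k * npix;
      double* g = dzd.memptr() + (R_xlen_t)k * npix;
      for (R_xlen_t i = 0; i < npix; ++i) {
        double w = target_prob[i];
        if (w <= 0) continue;
        double diff = dv[i] - tv[i];
        dl += w * std::fabs(diff);
        double s = diff > 0 ? 1.0 : (diff < 0 ? -1.0 : 0.0);
        double z = zd.memptr()[(R_xlen_t)k * npix + i];
        g[i] = lambda * w * s * sigmoid(z) / (nrays * wsum);
      }
    }
    dl /= (nrays * wsum);
  }
  double loss = bce + lambda * dl;
  out["loss"] = loss;
  out["bce"] = bce;
  out["dist_loss"] = dl;
  if (!want_grad) return out;

  // backward
  std::vector<mat> dWs(spec.size());
  std::vector<vec> dbs(spec.size());
  cube dcur_p = conv_backward(layers[hp], ctx[hp], 1, false, dzp, dWs[hp], dbs[hp]);
  cube dcur_d = conv_backward(layers[hd], ctx[hd], 1, false, dzd, dWs[hd], dbs[hd]);
  cube dcur = dcur_p + dcur_d;
  li = hp - 1;
  std::vector<cube> dskips(depth);
  for (int d = 0; d < depth; ++d) {
    dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
    dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
    // dcur is gradient w.r.t. concat(up, skip[d])
    int cup = dcur.n_slices - skips[d].n_slices;
    dskips[d] = dcur.slices(cup, dcur.n_slices - 1);
    cube dup = dcur.slices(0, cup - 1);
    dcur = upsample2_backward(dup);
  }
  dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
  dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
  for (int d = depth - 1; d >= 0; --d) {
    dcur = maxpool2_backward(dcur, argmaxes[d],
                             skips[d].n_rows, skips[d].n_cols);
    dcur += dskips[d];
    dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
    dcur = conv_backward(layers[li], ctx[li], 3, true, dcur, dWs[li], dbs[li]); --li;
  }

  NumericVector grad(params.size());
  R_xlen_t off = 0;
  for (size_t i = 0; i < spec.size(); ++i) {
    std::copy(dWs[i].memptr(), dWs[i].memptr() + dWs[i].n_elem, grad.begin() + off);
    off += dWs[i].n_elem;
    std::copy(dbs[i].memptr(), dbs[i].memptr() + dbs[i].n_elem, grad.begin() + off);
    off += dbs[i].n_elem;
  }
  out["grad"] = grad;
  return out;
}
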