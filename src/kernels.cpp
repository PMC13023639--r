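// Low-level numerical kernels for the segmentation toolkit.
// Array layout convention: feature maps are R arrays dim = c(H, W, C),
// column-major, element (i, j, c) (0-based) at i + H*j + H*W*c.
// Coordinates are 0-based pixel-center: x = column, y = row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// im2col / valid convolution with stride (input assumed pre-padded)
// ---------------------------------------------------------------------------

// map a (possibly out-of-range) index into [0, n-1] under a border mode:
// 0 = zero padding (returns -1), 1 = reflect, 2 = replicate
static inline int border_idx(int v, int n, int mode) {
  if (v >= 0 && v < n) return v;
  if (mode == 0) return -1;
  if (mode == 2) return v < 0 ? 0 : n - 1;
  if (n == 1) return 0;
  int per = 2 * (n - 1);
  int m = v % per; if (m < 0) m += per;
  return m > n - 1 ? per - m : m;
}

static arma::mat build_col(const double *x, int H, int W, int C,
                           int kh, int kw, int stride, int pad,
                           int mode, int Ho, int Wo) {
  arma::mat col(Ho * (size_t)Wo, (size_t)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        size_t q = (size_t)ih + (size_t)kh * iw + (size_t)kh * kw * c;
        double *dst = col.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          int j = border_idx(ow * stride + iw - pad, W, mode);
          for (int oh = 0; oh < Ho; ++oh) {
            int i = border_idx(oh * stride + ih - pad, H, mode);
            dst[(size_t)oh + (size_t)Ho * ow] =
                (i < 0 || j < 0) ? 0.0 : xc[(size_t)H * j + i];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector b, int stride, int pad, int mode) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1, Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than input");
  arma::mat col = build_col(REAL(x), H, W, C, kh, kw, stride, pad, mode, Ho, Wo);
  arma::mat wm(const_cast<double *>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat out = col * wm;
  if (b.size() == (R_xlen_t)Cout) {
    for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy, int stride, int pad, int mode, bool need_dx) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  int Ho = (H + 2 * pad - kh) / stride + 1, Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat dym(const_cast<double *>(REAL(dy)), (size_t)Ho * Wo, Cout, false, true);
  arma::mat col = build_col(REAL(x), H, W, C, kh, kw, stride, pad, mode, Ho, Wo);
  arma::mat dw = col.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  NumericVector dwv(dw.begin(), dw.end());
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector dbv(db.begin(), db.end());
  NumericVector dxv;
  if (need_dx) {
    arma::mat wm(const_cast<double *>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);
    arma::mat dcol = dym * wm.t();  // (Ho*Wo) x (kh*kw*C)
    dxv = NumericVector((size_t)H * W * C);
    double *dx = REAL(dxv);
    for (int c = 0; c < C; ++c) {
      double *dxc = dx + (size_t)H * W * c;
      for (int iw = 0; iw < kw; ++iw) {
        for (int ih = 0; ih < kh; ++ih) {
          size_t q = (size_t)ih + (size_t)kh * iw + (size_t)kh * kw * c;
          const double *src = dcol.colptr(q);
          for (int ow = 0; ow < Wo; ++ow) {
            int j = border_idx(ow * stride + iw - pad, W, mode);
            if (j < 0) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              int i = border_idx(oh * stride + ih - pad, H, mode);
              if (i < 0) continue;
              dxc[(size_t)H * j + i] += src[(size_t)oh + (size_t)Ho * ow];
            }
          }
        }
      }
    }
    dxv.attr("dim") = IntegerVector::create(H, W, C);
  }
  return List::create(_["dw"] = dwv, _["db"] = dbv, _["dx"] = dxv);
}

// ---------------------------------------------------------------------------
// Bilinear grid sampling. Rows (y) optionally wrap (periodic axis, e.g. theta);
// otherwise both axes use border (replicate) handling.
// ---------------------------------------------------------------------------

struct TapIdx { int i0, i1, j0, j1; double wy, wx; bool in_y, in_x; };

static inline TapIdx tap_at(double gy, double gx, int H, int W, bool wrap_rows) {
  TapIdx t;
  t.in_x = (gx > 0.0 && gx < (double)(W - 1));
  double x = gx < 0 ? 0 : (gx > W - 1 ? W - 1 : gx);
  t.j0 = (int)std::floor(x);
  if (t.j0 > W - 2) t.j0 = W >= 2 ? W - 2 : 0;
  t.j1 = clampi(t.j0 + 1, 0, W - 1);
  t.wx = x - t.j0;
  if (wrap_rows) {
    double y = gy - (double)H * std::floor(gy / (double)H);
    if (y < 0) y += H;
    if (y >= H) y = 0;
    t.i0 = (int)std::floor(y);
    if (t.i0 >= H) t.i0 = H - 1;
    t.i1 = (t.i0 + 1) % H;
    t.wy = y - t.i0;
    t.in_y = true;
  } else {
    t.in_y = (gy > 0.0 && gy < (double)(H - 1));
    double y = gy < 0 ? 0 : (gy > H - 1 ? H - 1 : gy);
    t.i0 = (int)std::floor(y);
    if (t.i0 > H - 2) t.i0 = H >= 2 ? H - 2 : 0;
    t.i1 = clampi(t.i0 + 1, 0, H - 1);
    t.wy = y - t.i0;
  }
  return t;
}

// [[Rcpp::export(name = ".grid_sample_fwd")]]
NumericVector grid_sample_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector gy, NumericVector gx,
                              bool wrap_rows) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  R_xlen_t n = gy.size();
  NumericVector out(n * (R_xlen_t)C);
  const double *xp = REAL(x);
  for (R_xlen_t k = 0; k < n; ++k) {
    TapIdx t = tap_at(gy[k], gx[k], H, W, wrap_rows);
    double w00 = (1 - t.wy) * (1 - t.wx), w10 = t.wy * (1 - t.wx);
    double w01 = (1 - t.wy) * t.wx, w11 = t.wy * t.wx;
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)H * W * c;
      out[k + n * (R_xlen_t)c] =
          w00 * xc[t.i0 + (size_t)H * t.j0] + w10 * xc[t.i1 + (size_t)H * t.j0] +
          w01 * xc[t.i0 + (size_t)H * t.j1] + w11 * xc[t.i1 + (size_t)H * t.j1];
    }
  }
  out.attr("dim") = IntegerVector::create((int)n, C);
  return out;
}

// [[Rcpp::export(name = ".grid_sample_bwd")]]
List grid_sample_bwd(NumericVector x, IntegerVector xdim,
                     NumericVector gy, NumericVector gx,
                     bool wrap_rows, NumericVector dout,
                     bool need_dx, bool need_dcoord) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  R_xlen_t n = gy.size();
  NumericVector dxv, dgy, dgx;
  double *dx = nullptr;
  if (need_dx) {
    dxv = NumericVector((size_t)H * W * C);
    dxv.attr("dim") = IntegerVector::create(H, W, C);
    dx = REAL(dxv);
  }
  if (need_dcoord) { dgy = NumericVector(n); dgx = NumericVector(n); }
  const double *xp = REAL(x);
  for (R_xlen_t k = 0; k < n; ++k) {
    TapIdx t = tap_at(gy[k], gx[k], H, W, wrap_rows);
    double w00 = (1 - t.wy) * (1 - t.wx), w10 = t.wy * (1 - t.wx);
    double w01 = (1 - t.wy) * t.wx, w11 = t.wy * t.wx;
    for (int c = 0; c < C; ++c) {
      double g = dout[k + n * (R_xlen_t)c];
      size_t off = (size_t)H * W * c;
      if (need_dx) {
        dx[off + t.i0 + (size_t)H * t.j0] += g * w00;
        dx[off + t.i1 + (size_t)H * t.j0] += g * w10;
        dx[off + t.i0 + (size_t)H * t.j1] += g * w01;
        dx[off + t.i1 + (size_t)H * t.j1] += g * w11;
      }
      if (need_dcoord) {
        const double *xc = xp + off;
        double v00 = xc[t.i0 + (size_t)H * t.j0], v10 = xc[t.i1 + (size_t)H * t.j0];
        double v01 = xc[t.i0 + (size_t)H * t.j1], v11 = xc[t.i1 + (size_t)H * t.j1];
        if (t.in_y)
          dgy[k] += g * ((1 - t.wx) * (v10 - v00) + t.wx * (v11 - v01));
        if (t.in_x)
          dgx[k] += g * ((1 - t.wy) * (v01 - v00) + t.wy * (v11 - v10));
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dgy"] = dgy, _["dgx"] = dgx);
}

// ---------------------------------------------------------------------------
// 3x3 max pooling, stride 1, replicate border (per channel)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".maxpool3_fwd")]]
List maxpool3_fwd(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector out((size_t)H * W * C);
  IntegerVector arg((size_t)H * W * C);
  const double *xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)H * W * c;
    size_t off = (size_t)H * W * c;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double best = -INFINITY; int bidx = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = clampi(j + dj, 0, W - 1);
          for (int di = -1; di <= 1; ++di) {
            int ii = clampi(i + di, 0, H - 1);
            double v = xc[ii + (size_t)H * jj];
            if (v > best) { best = v; bidx = ii + H * jj; }
          }
        }
        out[off + i + (size_t)H * j] = best;
        arg[off + i + (size_t)H * j] = bidx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool3_bwd")]]
NumericVector maxpool3_bwd(NumericVector dy, IntegerVector xdim, IntegerVector arg) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector dx((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    size_t off = (size_t)H * W * c;
    for (size_t k = 0; k < (size_t)H * W; ++k) dx[off + arg[off + k]] += dy[off + k];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// ---------------------------------------------------------------------------
// Circular depthwise convolution along the first (angular) axis
// x: (T, R, C), w: (L, C), L odd, centered; correlation semantics
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".dwtheta_fwd")]]
NumericVector dwtheta_fwd(NumericVector x, IntegerVector xdim, NumericMatrix w) {
  int T = xdim[0], R = xdim[1], C = xdim[2];
  int L = w.nrow(), mid = (L + 1) / 2;
  NumericVector out((size_t)T * R * C);
  const double *xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      const double *col = xp + (size_t)T * (r + (size_t)R * c);
      double *oc = REAL(out) + (size_t)T * (r + (size_t)R * c);
      for (int l = 0; l < L; ++l) {
        double wl = w(l, c);
        if (wl == 0) continue;
        int sh = l + 1 - mid;  // shift applied to source index
        for (int t = 0; t < T; ++t) {
          int s = t + sh;
          if (s < 0) s += T; else if (s >= T) s -= T;
          oc[t] += wl * col[s];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(T, R, C);
  return out;
}

// [[Rcpp::export(name = ".dwtheta_bwd")]]
List dwtheta_bwd(NumericVector x, IntegerVector xdim, NumericMatrix w,
                 NumericVector dy) {
  int T = xdim[0], R = xdim[1], C = xdim[2];
  int L = w.nrow(), mid = (L + 1) / 2;
  NumericVector dx((size_t)T * R * C);
  NumericMatrix dw(L, w.ncol());
  const double *xp = REAL(x), *dyp = REAL(dy);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      size_t off = (size_t)T * (r + (size_t)R * c);
      const double *col = xp + off, *gc = dyp + off;
      double *dc = REAL(dx) + off;
      for (int l = 0; l < L; ++l) {
        double wl = w(l, c), acc = 0;
        int sh = l + 1 - mid;
        for (int t = 0; t < T; ++t) {
          int s = t + sh;
          if (s < 0) s += T; else if (s >= T) s -= T;
          dc[s] += wl * gc[t];
          acc += gc[t] * col[s];
        }
        dw(l, c) += acc;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(T, R, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------------------------
// Nearest-neighbour distances between two 2-D point sets (rows = points)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nn_min_dist")]]
NumericVector nn_min_dist(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = INFINITY;
    double ax = a(i, 0), ay = a(i, 1);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
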