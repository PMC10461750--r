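// Numeric kernels: exact Euclidean distance transform, skeleton thinning,
// 2-D convolution forward/backward (im2col), 2x2 max pooling, bilinear x2
// upsampling, normalized cross-correlation, velocity-profile rasterization
// and sub-pixel PSF splatting. All image tensors are H x W (x C) doubles,
// row = axial (depth), col = lateral.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Felzenszwalb & Huttenlocher 1-D squared distance transform
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance to the nearest background (FALSE) pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  const double BIG = 1e18;
  // columns first
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  arma::mat tmp(H, W);
  for (int j = 0; j < W; ++j) {
    f.assign(H, 0.0);
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? BIG : 0.0;
    d.assign(H, 0.0);
    dt1d(f, d);
    for (int i = 0; i < H; ++i) tmp(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    f.assign(W, 0.0);
    for (int j = 0; j < W; ++j) f[j] = tmp(i, j);
    d.assign(W, 0.0);
    dt1d(f, d);
    for (int j = 0; j < W; ++j) out(i, j) = d[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning to a one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // pad by 1 to avoid bound checks
  std::vector<unsigned char> img((H + 2) * (W + 2), 0);
  auto at = [&](int i, int j) -> unsigned char& {
    return img[(i + 1) + (j + 1) * (H + 2)];
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) at(i, j) = mask(i, j) ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!at(i, j)) continue;
          // neighbours P2..P9 clockwise starting at north
          unsigned char p2 = at(i - 1, j), p3 = at(i - 1, j + 1),
                        p4 = at(i, j + 1), p5 = at(i + 1, j + 1),
                        p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
                        p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        at(kill[t].first, kill[t].second) = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = at(i, j) != 0;
  return out;
}

// ---------------------------------------------------------------------------
// im2col for odd kernel k with zero padding (k-1)/2; pixel order column-major.
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat M(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colIdx = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = &x(i0 + di, j + dj, c);
          double* dst = M.colptr(colIdx) + (i0 + (size_t)H * j);
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return M;
}

static arma::cube col2im(const arma::mat& M, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colIdx = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = M.colptr(colIdx) + (i0 + (size_t)H * j);
          double* dst = &x(i0 + di, j + dj, c);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return x;
}

// W: (k*k*Cin) x Cout, matching R's flatten of array(k, k, Cin, Cout).
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  arma::mat M = im2col(x, k);
  arma::mat Y = M * W;
  Y.each_row() += b.t();
  arma::cube out(H, Wd, W.n_cols);
  for (arma::uword c = 0; c < W.n_cols; ++c)
    out.slice(c) = arma::reshape(Y.col(c), H, Wd);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& gy, int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat Gy(H * Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    Gy.col(c) = arma::vectorise(gy.slice(c));
  arma::mat M = im2col(x, k);
  arma::mat gW = M.t() * Gy;
  arma::vec gb = arma::sum(Gy, 0).t();
  arma::mat Gx = Gy * W.t();
  arma::cube gx = col2im(Gx, H, Wd, Cin, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2). idx holds 0-based linear index into the input
// slice of the winning element.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -INFINITY;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = ii + (arma::uword)H * jj;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::ucube& idx, const arma::cube& gy,
                           int H, int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slc = gx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        slc[idx(i, j, c)] += gy(i, j, c);
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Bilinear x2 upsampling, align_corners = FALSE convention: output sample i
// maps to input coordinate (i + 0.5)/2 - 0.5.
static void up2_weights(int n_out, int n_in, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(n_out);
  i1.resize(n_out);
  w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(u);
    double f = u - a;
    if (a < 0) { a = 0; f = 0.0; }
    if (a >= n_in - 1) { a = n_in - 1; f = 0.0; }
    i0[i] = a;
    i1[i] = std::min(a + 1, n_in - 1);
    w1[i] = f;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, r0, r1, rw);
  up2_weights(Wo, W, c0, c1, cw);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) =
            (1 - rw[i]) * (1 - cw[j]) * x(r0[i], c0[j], c) +
            rw[i] * (1 - cw[j]) * x(r1[i], c0[j], c) +
            (1 - rw[i]) * cw[j] * x(r0[i], c1[j], c) +
            rw[i] * cw[j] * x(r1[i], c1[j], c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy, int H, int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, r0, r1, rw);
  up2_weights(Wo, W, c0, c1, cw);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gy(i, j, c);
        gx(r0[i], c0[j], c) += (1 - rw[i]) * (1 - cw[j]) * g;
        gx(r1[i], c0[j], c) += rw[i] * (1 - cw[j]) * g;
        gx(r0[i], c1[j], c) += (1 - rw[i]) * cw[j] * g;
        gx(r1[i], c1[j], c) += rw[i] * cw[j] * g;
      }
  return gx;
}

// ---------------------------------------------------------------------------
// Zero-normalized cross-correlation of a template against every fully
// contained window; scores at window centres, borders left at 0.
// [[Rcpp::export]]
NumericMatrix cpp_ncc(const arma::mat& img, const arma::mat& tmpl) {
  const int H = img.n_rows, W = img.n_cols;
  const int th = tmpl.n_rows, tw = tmpl.n_cols;
  const int ph = th / 2, pw = tw / 2;
  NumericMatrix out(H, W);
  const double tm = arma::mean(arma::vectorise(tmpl));
  arma::mat t0 = tmpl - tm;
  const double tnorm = std::sqrt(arma::accu(t0 % t0));
  if (tnorm == 0) return out;
  const double n = (double)th * tw;
  for (int j = pw; j + tw - pw <= W; ++j) {
    for (int i = ph; i + th - ph <= H; ++i) {
      const arma::mat w = img.submat(i - ph, j - pw, i - ph + th - 1,
                                     j - pw + tw - 1);
      const double wm = arma::accu(w) / n;
      double num = 0.0, den = 0.0;
      for (int b = 0; b < tw; ++b)
        for (int a = 0; a < th; ++a) {
          const double d = w(a, b) - wm;
          num += d * t0(a, b);
          den += d * d;
        }
      out(i, j) = den > 0 ? num / (std::sqrt(den) * tnorm) : 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize a laminar velocity profile around a centerline path onto
// magnitude/angle grids (max-magnitude wins on overlap). path holds 1-based
// (row, col) coordinates; theta the local tangent angle per point.
// [[Rcpp::export]]
void cpp_rasterize_profile(NumericMatrix mag, NumericMatrix ang,
                           const NumericMatrix& path, const NumericVector& radii,
                           const NumericVector& theta, double vref,
                           double expo) {
  const int H = mag.nrow(), W = mag.ncol();
  for (int p = 0; p < path.nrow(); ++p) {
    const double cr = path(p, 0), cc = path(p, 1), r = radii[p];
    if (!(r > 0)) continue;
    const int i0 = std::max(0, (int)std::floor(cr - r) - 1);
    const int i1 = std::min(H - 1, (int)std::ceil(cr + r));
    const int j0 = std::max(0, (int)std::floor(cc - r) - 1);
    const int j1 = std::min(W - 1, (int)std::ceil(cc + r));
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        const double dr = (i + 1) - cr, dc = (j + 1) - cc;
        const double d = std::sqrt(dr * dr + dc * dc);
        if (d > r) continue;
        const double m = vref * (1.0 - std::pow(d / r, expo));
        if (m > mag(i, j)) {
          mag(i, j) = m;
          ang(i, j) = theta[p];
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Add `amp * patch` to `frame` centred at continuous 1-based (crow, ccol),
// distributing each patch pixel bilinearly over its four integer neighbours.
// [[Rcpp::export]]
void cpp_splat_patch(NumericMatrix frame, const NumericMatrix& patch,
                     double crow, double ccol, double amp) {
  const int H = frame.nrow(), W = frame.ncol();
  const int ph = patch.nrow(), pw = patch.ncol();
  const double pcr = (ph - 1) / 2.0, pcc = (pw - 1) / 2.0;
  for (int b = 0; b < pw; ++b) {
    for (int a = 0; a < ph; ++a) {
      const double v = amp * patch(a, b);
      if (v == 0) continue;
      const double tr = crow + (a - pcr) - 1.0;  // 0-based target
      const double tc = ccol + (b - pcc) - 1.0;
      const int r0 = (int)std::floor(tr), c0 = (int)std::floor(tc);
      const double fr = tr - r0, fc = tc - c0;
      const int rr[2] = {r0, r0 + 1};
      const int cc2[2] = {c0, c0 + 1};
      const double wr[2] = {1 - fr, fr};
      const double wc[2] = {1 - fc, fc};
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int ri = rr[di], ci = cc2[dj];
          if (ri < 0 || ri >= H || ci < 0 || ci >= W) continue;
          frame(ri, ci) += v * wr[di] * wc[dj];
        }
    }
  }
}

// ---------------------------------------------------------------------------
// Resample a patch under rotation (radians) and anisotropic scaling about its
// centre (inverse mapping, bilinear, zero outside).
// [[Rcpp::export]]
NumericMatrix cpp_transform_patch(const NumericMatrix& patch, double angle,
                                  double srow, double scol) {
  const int ph = patch.nrow(), pw = patch.ncol();
  const double pcr = (ph - 1) / 2.0, pcc = (pw - 1) / 2.0;
  NumericMatrix out(ph, pw);
  const double ca = std::cos(-angle), sa = std::sin(-angle);
  for (int j = 0; j < pw; ++j) {
    for (int i = 0; i < ph; ++i) {
      const double dr = (i - pcr) / srow, dc = (j - pcc) / scol;
      const double sr = ca * dr - sa * dc + pcr;
      const double sc = sa * dr + ca * dc + pcc;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 < -1 || r0 > ph - 1 || c0 < -1 || c0 > pw - 1) continue;
      const double fr = sr - r0, fc = sc - c0;
      double acc = 0.0;
      const int rr[2] = {r0, r0 + 1};
      const int cc2[2] = {c0, c0 + 1};
      const double wr[2] = {1 - fr, fr};
      const double wc[2] = {1 - fc, fc};
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int ri = rr[di], ci = cc2[dj];
          if (ri < 0 || ri >= ph || ci < 0 || ci >= pw) continue;
          acc += patch(ri, ci) * wr[di] * wc[dj];
        }
      out(i, j) = acc;
    }
  }
  return out;
}
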