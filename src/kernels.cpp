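// Numerical kernels for the convolutional encoder/decoder: 2-d convolution
// and bilinear resizing, forward and backward. Arrays are R arrays in
// [H, W, C, N] layout (column-major), weights [kh, kw, Cin, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int d[4]) {
  if (!x.hasAttribute("dim")) stop("expected a 4-d array");
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; i++) d[i] = dim[i];
}

// im2col for one image: x (H,W,C) -> col (K x P), K = kh*kw*C, P = Ho*Wo,
// column index p = ho + Ho*wo, row index r = ki + kh*(kj + kw*c) so that it
// matches the column-major flattening of the [kh,kw,Cin] weight block.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  const int K = kh * kw * C;
  for (int c = 0; c < C; c++) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; kj++) {
      for (int ki = 0; ki < kh; ki++) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; wo++) {
          const int wi = wo * stride - pad + kj;
          double* dst = col.memptr() + r + (size_t)K * (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ho++) dst[(size_t)K * ho] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ho++) {
            const int hi = ho * stride - pad + ki;
            dst[(size_t)K * ho] =
                (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  const int K = kh * kw * C;
  for (int c = 0; c < C; c++) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; kj++) {
      for (int ki = 0; ki < kh; ki++) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; wo++) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* src = col.memptr() + r + (size_t)K * (size_t)Ho * wo;
          double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ho++) {
            const int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H) xcol[hi] += src[(size_t)K * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  if (dw[2] != C) stop("conv2d: input channel mismatch");
  if (b.size() != Co) stop("conv2d: bias length mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, Co, false, true);
  arma::rowvec bv(b.begin(), Co);
  NumericVector y((R_xlen_t)P * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat Ym(y.begin() + (size_t)n * P * Co, P, Co, false, true);
    Ym = col.t() * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, bool need_dx = true) {
  int dx_[4], dw_[4], dy_[4];
  get_dims4(x, dx_); get_dims4(w, dw_); get_dims4(dy, dy_);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Co = dw_[3];
  const int Ho = dy_[0], Wo = dy_[1];
  if (dy_[2] != Co || dy_[3] != N) stop("conv2d_bw: dy shape mismatch");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, Co, false, true);
  NumericVector dxv((R_xlen_t)x.size());
  dxv.attr("dim") = x.attr("dim");
  NumericVector dwv((R_xlen_t)w.size());
  dwv.attr("dim") = w.attr("dim");
  NumericVector dbv(Co);
  arma::mat dWm(dwv.begin(), K, Co, false, true);
  arma::rowvec db(dbv.begin(), Co, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat dYm(dy.begin() + (size_t)n * P * Co, P, Co, false, true);
    dWm += col * dYm;
    db += arma::sum(dYm, 0);
    if (need_dx) {
      arma::mat dcol = Wm * dYm.t();
      col2im_add(dcol, dxv.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
                 stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               Nullable<NumericVector> mu_, Nullable<NumericVector> var_,
               double eps) {
  int d[4];
  get_dims4(x, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector mu(C), var(C);
  bool batch_stats = mu_.isNull();
  if (batch_stats) {
    for (int c = 0; c < C; c++) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; n++) {
        const double* p = x.begin() + (size_t)HW * (c + (size_t)C * n);
        for (int i = 0; i < HW; i++) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = (double)HW * N;
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
    }
  } else {
    mu = NumericVector(mu_);
    var = NumericVector(var_);
  }
  NumericVector xhat((R_xlen_t)x.size()), y((R_xlen_t)x.size());
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  NumericVector inv_std(C);
  for (int c = 0; c < C; c++) inv_std[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* p = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double* ph = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double* py = y.begin() + (size_t)HW * (c + (size_t)C * n);
      const double is = inv_std[c], m0 = mu[c], g = gamma[c], b = beta[c];
      for (int i = 0; i < HW; i++) {
        ph[i] = (p[i] - m0) * is;
        py[i] = ph[i] * g + b;
      }
    }
  }
  return List::create(_["out"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["inv_std"] = inv_std);
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector xhat, NumericVector dy, NumericVector gamma,
               NumericVector inv_std, bool train) {
  int d[4];
  get_dims4(dy, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* ph = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + (size_t)HW * (c + (size_t)C * n);
      double sg = 0, sb = 0;
      for (int i = 0; i < HW; i++) { sg += pd[i] * ph[i]; sb += pd[i]; }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  }
  NumericVector dx((R_xlen_t)dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double m = (double)HW * N;
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* ph = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + (size_t)HW * (c + (size_t)C * n);
      double* px = dx.begin() + (size_t)HW * (c + (size_t)C * n);
      const double gs = gamma[c] * inv_std[c];
      if (train) {
        const double a = gs / m, dg = dgamma[c], db = dbeta[c];
        for (int i = 0; i < HW; i++) {
          px[i] = a * (m * pd[i] - db - ph[i] * dg);
        }
      } else {
        for (int i = 0; i < HW; i++) px[i] = gs * pd[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Bilinear affine warp of a matrix; inv is the 3x3 output->source
// transform in 0-based (x, y) pixel coordinates; zero outside.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix m, NumericMatrix inv) {
  const int H = m.nrow(), W = m.ncol();
  NumericMatrix out(H, W);
  const double a11 = inv(0, 0), a12 = inv(0, 1), a13 = inv(0, 2);
  const double a21 = inv(1, 0), a22 = inv(1, 1), a23 = inv(1, 2);
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) {
      const double sx = a11 * j + a12 * i + a13;
      const double sy = a21 * j + a22 * i + a23;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      double v = 0;
      for (int dy = 0; dy <= 1; dy++) {
        const int y = y0 + dy;
        if (y < 0 || y >= H) continue;
        const double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx <= 1; dx++) {
          const int x = x0 + dx;
          if (x < 0 || x >= W) continue;
          v += m(y, x) * wy * (dx ? fx : 1 - fx);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Block-max pooling of a matrix to grid_h x grid_w cells.
// [[Rcpp::export]]
NumericMatrix block_max_cpp(NumericMatrix m, int grid_h, int grid_w) {
  const int H = m.nrow(), W = m.ncol();
  const int bh = H / grid_h, bw = W / grid_w;
  NumericMatrix out(grid_h, grid_w);
  for (int gj = 0; gj < grid_w; gj++) {
    for (int gi = 0; gi < grid_h; gi++) {
      double mx = R_NegInf;
      for (int j = gj * bw; j < (gj + 1) * bw; j++) {
        const double* col = &m(0, j);
        for (int i = gi * bh; i < (gi + 1) * bh; i++) {
          if (col[i] > mx) mx = col[i];
        }
      }
      out(gi, gj) = mx;
    }
  }
  return out;
}

struct ResampleIdx {
  std::vector<int> i0, i1;
  std::vector<double> f;
};

// Half-pixel-center source coordinates, clamped to the valid range.
static ResampleIdx bilinear_index(int n_out, int n_in) {
  ResampleIdx r;
  r.i0.resize(n_out); r.i1.resize(n_out); r.f.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; i++) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    if (i0 > n_in - 1) i0 = n_in - 1;
    r.i0[i] = i0;
    r.i1[i] = std::min(i0 + 1, n_in - 1);
    r.f[i] = s - i0;
  }
  return r;
}

// [[Rcpp::export]]
NumericVector bilinear_fw(NumericVector x, int ho, int wo) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (ho <= 0 || wo <= 0) stop("bilinear_fw: non-positive output size");
  ResampleIdx ri = bilinear_index(ho, H), rj = bilinear_index(wo, W);
  NumericVector y((R_xlen_t)ho * wo * C * N);
  y.attr("dim") = IntegerVector::create(ho, wo, C, N);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)ho * wo * (c + (size_t)C * n);
      for (int j = 0; j < wo; j++) {
        const double* x0 = xp + (size_t)H * rj.i0[j];
        const double* x1 = xp + (size_t)H * rj.i1[j];
        const double fj = rj.f[j];
        for (int i = 0; i < ho; i++) {
          const double fi = ri.f[i];
          const double top = x0[ri.i0[i]] * (1 - fj) + x1[ri.i0[i]] * fj;
          const double bot = x0[ri.i1[i]] * (1 - fj) + x1[ri.i1[i]] * fj;
          yp[i + (size_t)ho * j] = top * (1 - fi) + bot * fi;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bw(NumericVector dy, int h, int w) {
  int d[4];
  get_dims4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  ResampleIdx ri = bilinear_index(Ho, h), rj = bilinear_index(Wo, w);
  NumericVector dx((R_xlen_t)h * w * C * N);
  dx.attr("dim") = IntegerVector::create(h, w, C, N);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)h * w * (c + (size_t)C * n);
      for (int j = 0; j < Wo; j++) {
        double* x0 = dxp + (size_t)h * rj.i0[j];
        double* x1 = dxp + (size_t)h * rj.i1[j];
        const double fj = rj.f[j];
        for (int i = 0; i < Ho; i++) {
          const double fi = ri.f[i];
          const double g = dyp[i + (size_t)Ho * j];
          x0[ri.i0[i]] += g * (1 - fj) * (1 - fi);
          x1[ri.i0[i]] += g * fj * (1 - fi);
          x0[ri.i1[i]] += g * (1 - fj) * fi;
          x1[ri.i1[i]] += g * fj * fi;
        }
      }
    }
  }
  return dx;
}
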