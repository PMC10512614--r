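// Low-level kernels for the convolutional engine and image geometry.
// Layout convention: activations are column-major R arrays with
// dim = (H, W, C, N); weights dim = (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad_lo, int pad_hi) {
  return (in + pad_lo + pad_hi - k) / stride + 1;
}

// Gather the im2col matrix (kh*kw*Cin x Ho*Wo) for one sample.
// x points to an (H, W, C) slice. Zero padding, symmetric `pad`.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int row = u + kh * (v + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + v - pad;
          const bool jok = (j >= 0 && j < W);
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + u - pad;
            double val = 0.0;
            if (jok && i >= 0 && i < H)
              val = x[i + (size_t)H * (j + (size_t)W * c)];
            col(row, io + (size_t)Ho * jo) = val;
          }
        }
      }
    }
  }
}

// Scatter-accumulate a col-matrix back into an (H, W, C) gradient slice.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int row = u + kh * (v + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + v - pad;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + u - pad;
            if (i < 0 || i >= H) continue;
            dx[i + (size_t)H * (j + (size_t)W * c)] += col(row, io + (size_t)Ho * jo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad, pad);
  const int Wo = out_size(W, kw, stride, pad, pad);
  NumericVector y(Ho * (size_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const int K = kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true); // (K x Cout)
  arma::mat col(K, (size_t)Ho * Wo);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)H * W * C * n;
    double* ys = y.begin() + (size_t)Ho * Wo * Cout * n;
    im2col(xs, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ym = col.t() * Wm;                    // (Ho*Wo x Cout)
    ym.each_row() += bv.t();
    std::copy(ym.memptr(), ym.memptr() + ym.n_elem, ys);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)H * W * C * n;
    double* dxs = dx.begin() + (size_t)H * W * C * n;
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col(xs, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dWm += col * dym;                               // (K x Cout)
    dbv += arma::sum(dym, 0).t();
    arma::mat dcol = Wm * dym.t();                  // (K x Ho*Wo)
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo, dxs);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling with optional extra zero padding on the bottom/right edge
// (pad_rb in {0,1}); padded cells never win the max.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad_rb) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, 0, pad_rb);
  const int Wo = out_size(W, k, stride, 0, pad_rb);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);   // 1-based linear index into sample slice
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)H * W * C * n;
    double* ys = y.begin() + (size_t)Ho * Wo * C * n;
    int* is = idx.begin() + (size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = R_NegInf; int besti = -1;
          for (int v = 0; v < k; ++v) {
            const int j = jo * stride + v;
            if (j >= W) continue;
            for (int u = 0; u < k; ++u) {
              const int i = io * stride + u;
              if (i >= H) continue;
              const double val = xs[i + (size_t)H * (j + (size_t)W * c)];
              if (val > best) { best = val; besti = i + H * (j + W * c); }
            }
          }
          ys[io + (size_t)Ho * (jo + (size_t)Wo * c)] = best;
          is[io + (size_t)Ho * (jo + (size_t)Wo * c)] = besti + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector in_dim, IntegerVector idx, NumericVector dy) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector yd = dy.attr("dim");
  const size_t per_out = (size_t)yd[0] * yd[1] * yd[2];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n) {
    const int* is = idx.begin() + per_out * n;
    const double* dys = dy.begin() + per_out * n;
    double* dxs = dx.begin() + (size_t)H * W * C * n;
    for (size_t q = 0; q < per_out; ++q) dxs[is[q] - 1] += dys[q];
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          ys[i + (size_t)Ho * j] = xs[(i / f) + (size_t)H * (j / f)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector dy, int f) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / f, W = Wo / f;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dys = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dxs[(i / f) + (size_t)H * (j / f)] += dys[i + (size_t)Ho * j];
    }
  return dx;
}

// Rotate a 2-D matrix about its center by `angle` degrees (counter-clockwise
// in pixel coordinates), keeping the frame size; out-of-frame samples are 0.
// bilinear = false gives nearest-neighbor resampling (mask-safe).
// [[Rcpp::export]]
NumericMatrix cpp_rotate(NumericMatrix x, double angle, bool bilinear) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double dr = i - cr, dc = j - cc;
      const double sr = cr + ct * dr + st * dc;
      const double sc = cc - st * dr + ct * dc;
      if (bilinear) {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        double acc = 0.0;
        for (int dj = 0; dj <= 1; ++dj)
          for (int di = 0; di <= 1; ++di) {
            const int r = r0 + di, c = c0 + dj;
            if (r < 0 || r >= H || c < 0 || c >= W) continue;
            acc += x(r, c) * (di ? fr : 1 - fr) * (dj ? fc : 1 - fc);
          }
        y(i, j) = acc;
      } else {
        const int r = (int)std::lround(sr), c = (int)std::lround(sc);
        y(i, j) = (r >= 0 && r < H && c >= 0 && c < W) ? x(r, c) : 0.0;
      }
    }
  }
  return y;
}
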