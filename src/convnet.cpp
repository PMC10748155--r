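// Minimal 2-D convolution / max-pooling primitives for the 10-block CNN.
// Layout convention: feature maps are R arrays with dim (H, W, C, N),
// i.e. column-major with height fastest — matching arma::cube slices.
// Convolutions are stride-1 with zero "same" padding and odd square kernels;
// pooling is 2x2 stride 2 with floor semantics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col(const cube& x, int k, mat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  col.set_size(k * k * C, H * W);
  for (int c = 0; c < C; ++c) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dx = -p; dx <= p; ++dx) {
        const int r = c * k * k + (dy + p) * k + (dx + p);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          double* dst = col.colptr(w * H) + r;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) dst[(size_t)h * col.n_rows] = 0.0;
            continue;
          }
          const double* src = x.slice_colptr(c, ws);
          for (int h = 0; h < H; ++h) {
            const int hs = h + dy;
            dst[(size_t)h * col.n_rows] =
                (hs < 0 || hs >= H) ? 0.0 : src[hs];
          }
        }
      }
    }
  }
}

// Accumulate columns back into an image (adjoint of im2col).
static void col2im(const mat& col, int k, cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  x.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dx = -p; dx <= p; ++dx) {
        const int r = c * k * k + (dy + p) * k + (dx + p);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          double* dst = x.slice_colptr(c, ws);
          const double* src = col.colptr(w * H) + r;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dy;
            if (hs >= 0 && hs < H) dst[hs] += src[(size_t)h * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_forward(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                                   Rcpp::NumericVector b, int k) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.nrow();
  mat wm(w.begin(), F, w.ncol(), false);
  vec bv(b.begin(), F, false);
  Rcpp::NumericVector out((size_t)H * W * F * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, F, N);
  mat col;
  for (int n = 0; n < N; ++n) {
    const cube xn(const_cast<double*>(&x[0]) + (size_t)n * H * W * C,
                  H, W, C, false, true);
    im2col(xn, k, col);
    mat y = wm * col;            // F x (H*W)
    y.each_col() += bv;
    mat yt = y.t();              // (H*W) x F : matches (H,W,F) column-major
    std::copy(yt.begin(), yt.end(), out.begin() + (size_t)n * H * W * F);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                           Rcpp::NumericVector dy, int k) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.nrow();
  mat wm(w.begin(), F, w.ncol(), false);
  Rcpp::NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  mat dw(F, w.ncol(), fill::zeros);
  vec db(F, fill::zeros);
  mat col;
  cube dxi(H, W, C);
  for (int n = 0; n < N; ++n) {
    const cube xn(const_cast<double*>(&x[0]) + (size_t)n * H * W * C,
                  H, W, C, false, true);
    const mat dyt(const_cast<double*>(&dy[0]) + (size_t)n * H * W * F,
                  H * W, F, false, true);
    mat dym = dyt.t();           // F x (H*W)
    im2col(xn, k, col);
    dw += dym * col.t();
    db += sum(dym, 1);
    mat dcol = wm.t() * dym;     // (k*k*C) x (H*W)
    col2im(dcol, k, dxi);
    std::copy(dxi.begin(), dxi.end(), dx.begin() + (size_t)n * H * W * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
Rcpp::List maxpool_forward(Rcpp::NumericVector x) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  Rcpp::IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based into (H,W) plane
  idx.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  const double* xp = &x[0];
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const size_t offo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = -1; double bv = -datum::inf;
          for (int dw2 = 0; dw2 < 2; ++dw2) {
            for (int dh = 0; dh < 2; ++dh) {
              const int h = 2 * ho + dh, w = 2 * wo + dw2;
              const int li = h + H * w;
              const double v = xp[off + li];
              if (v > bv) { bv = v; best = li; }
            }
          }
          y[offo + ho + (size_t)Ho * wo] = bv;
          idx[offo + ho + (size_t)Ho * wo] = best;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector maxpool_backward(Rcpp::IntegerVector idx, Rcpp::NumericVector dy,
                                     int H, int W) {
  Rcpp::IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  Rcpp::NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const size_t offo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        dx[off + idx[offo + i]] += dy[offo + i];
    }
  }
  return dx;
}
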