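// Numerical kernels: same-padding 2-D convolution (forward/backward via
// im2col), exact squared Euclidean distance transform (two-pass lower
// envelope), and 8-connected component labelling. Arrays follow R's
// column-major layout: images are (H, W, C, N), weights (k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& cols) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = dh + k * dw + k * k * c;
        double* dst = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int wi = w + dw - pad;
          if (wi < 0 || wi >= W) {
            for (int h = 0; h < H; ++h) dst[h + H * w] = 0.0;
            continue;
          }
          const double* src = x + (size_t)H * (wi + (size_t)W * c);
          for (int h = 0; h < H; ++h) {
            const int hi = h + dh - pad;
            dst[h + H * w] = (hi < 0 || hi >= H) ? 0.0 : src[hi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, int H, int W, int C, int k,
                       double* gx) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = dh + k * dw + k * k * c;
        const double* src = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int wi = w + dw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = gx + (size_t)H * (wi + (size_t)W * c);
          for (int h = 0; h < H; ++h) {
            const int hi = h + dh - pad;
            if (hi >= 0 && hi < H) dst[hi] += src[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: weight Cin %d != input C %d", wd[2], C);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat Y = cols * Wm;
    Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false);
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat gW(k * k * C, Cout, arma::fill::zeros);
  arma::rowvec gB(Cout, arma::fill::zeros);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat G(const_cast<double*>(gy.begin()) + (size_t)H * W * Cout * n,
                H * W, Cout, false, true);
    gW += cols.t() * G;
    gB += arma::sum(G, 0);
    arma::mat Gc = G * Wm.t();
    col2im_add(Gc, H, W, C, k, gx.begin() + (size_t)H * W * C * n);
  }
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gWr,
                      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// 1-D squared-distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int q0 = 0;
  while (q0 < n && f[q0] == INFINITY) ++q0;
  if (q0 == n) { // nothing reachable on this scan line
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  int kk = 0;
  v[0] = q0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INFINITY) continue; // unreachable parabola, skip
    double s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) /
               (2.0 * q - 2.0 * v[kk]);
    while (s <= z[kk]) {
      --kk;
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// Exact squared Euclidean distance to the nearest non-zero pixel.
// All-background input returns +Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  const int nmax = std::max(H, W);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // columns
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = mask(h, w) != 0 ? 0.0 : INFINITY;
    dt1d(f, d, v, z, H);
    for (int h = 0; h < H; ++h) out(h, w) = d[h];
  }
  // rows
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) f[w] = out(h, w);
    dt1d(f, d, v, z, W);
    for (int w = 0; w < W; ++w) out(h, w) = d[w];
  }
  return out;
}

// 8-connected component labelling by iterative flood fill.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(h0, w0));
      lab(h0, w0) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dh = -1; dh <= 1; ++dh) {
          for (int dw = -1; dw <= 1; ++dw) {
            if (dh == 0 && dw == 0) continue;
            int h = p.first + dh, w = p.second + dw;
            if (h < 0 || h >= H || w < 0 || w >= W) continue;
            if (mask(h, w) != 0 && lab(h, w) == 0) {
              lab(h, w) = next;
              stack.push_back(std::make_pair(h, w));
            }
          }
        }
      }
    }
  }
  return lab;
}
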