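// Low-level numerical kernels: 2-D convolution (forward/backward) via
// im2col + GEMM, transposed convolution, max pooling, separable moving
// minimum / mean filters with edge replication, and 8-connected labeling.
// Array layout follows R: column-major, dims [H, W, C, N].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// cols(kh*kw*C x Hout*Wout) from one sample x (H x W x C slab of a big array)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout, arma::mat& cols) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int col = ho + Hout * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride + kj - pad;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride + ki - pad;
            const int row = ki + kh * (kj + kw * c);
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              cols(row, col) = x[hi + H * (wi + W * c)];
            else
              cols(row, col) = 0.0;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& cols, double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int col = ho + Hout * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            const int row = ki + kh * (kj + kw * c);
            x[hi + H * (wi + W * c)] += cols(row, col);
          }
        }
      }
    }
  }
}

// weight array w[kh,kw,Cin,Cout] -> matrix (Cout x kh*kw*Cin), row order
// matching im2col's row index ki + kh*(kj + kw*c)
static arma::mat weight_mat(const NumericVector& w, int kh, int kw,
                            int Cin, int Cout) {
  arma::mat W(Cout, kh * kw * Cin);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          W(o, ki + kh * (kj + kw * c)) =
            wp[ki + kh * (kj + kw * (c + Cin * o))];
  return W;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { // single sample -> N = 1
    IntegerVector d4(4);
    d4[0] = d[0]; d4[1] = d[1]; d4[2] = d[2]; d4[3] = 1;
    return d4;
  }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = dims4(x), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  if (Hout < 1 || Wout < 1) stop("conv2d: output would be empty");
  NumericVector y(static_cast<R_xlen_t>(Hout) * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout);
  arma::mat cols(kh * kw * C, Hout * Wout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C, H, W, C,
           kh, kw, stride, pad, Hout, Wout, cols);
    arma::mat ym = Wm * cols; // Cout x Hout*Wout
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Hout * Wout; ++p)
        yp[p + Hout * Wout * o] = ym(o, p) + b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = dims4(x), wd = w.attr("dim"), yd = dims4(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Hout = yd[0], Wout = yd[1];
  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout);
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  arma::mat dWm(Cout, kh * kw * Cin, arma::fill::zeros);
  NumericVector db(Cout);
  arma::mat cols(kh * kw * C, Hout * Wout);
  arma::mat dym(Cout, Hout * Wout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Hout * Wout; ++p)
        dym(o, p) = dyp[p + Hout * Wout * o];
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C, H, W, C,
           kh, kw, stride, pad, Hout, Wout, cols);
    dWm += dym * cols.t();
    for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dym.row(o));
    arma::mat dcols = Wm.t() * dym;
    col2im(dcols, dx.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, Hout, Wout);
  }
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  double* dwp = dw.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dwp[ki + kh * (kj + kw * (c + Cin * o))] =
            dWm(o, ki + kh * (kj + kw * c));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, weights w[kh,kw,Cin,Cout] mapping Cin -> Cout.
// Output size: (H-1)*stride + kh - 2*pad.
// [[Rcpp::export]]
NumericVector cpp_convT2d_forward(NumericVector x, NumericVector w,
                                  NumericVector b, int stride, int pad) {
  IntegerVector xd = dims4(x), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convT2d: input has %d channels, weights expect %d", C, Cin);
  const int Hout = (H - 1) * stride + kh - 2 * pad;
  const int Wout = (W - 1) * stride + kw - 2 * pad;
  // M: Cin x kh*kw*Cout, row order matching col2im rows over (ki,kj,o)
  arma::mat M(Cin, kh * kw * Cout);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          M(c, ki + kh * (kj + kw * o)) =
            wp[ki + kh * (kj + kw * (c + Cin * o))];
  NumericVector y(static_cast<R_xlen_t>(Hout) * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat xm(C, H * W);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) xm(c, p) = xp[p + H * W * c];
    arma::mat cols = M.t() * xm; // kh*kw*Cout x H*W
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * Cout;
    col2im(cols, yp, Hout, Wout, Cout, kh, kw, stride, pad, H, W);
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Hout * Wout; ++p)
        yp[p + Hout * Wout * o] += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convT2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                          int stride, int pad) {
  IntegerVector xd = dims4(x), wd = w.attr("dim"), yd = dims4(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Hout = yd[0], Wout = yd[1];
  arma::mat M(Cin, kh * kw * Cout);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          M(c, ki + kh * (kj + kw * o)) =
            wp[ki + kh * (kj + kw * (c + Cin * o))];
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  arma::mat dM(Cin, kh * kw * Cout, arma::fill::zeros);
  NumericVector db(Cout);
  arma::mat dcols(kh * kw * Cout, H * W);
  arma::mat xm(C, H * W);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * Cout;
    // gather: dcols(row over (ki,kj,o), col over input pos) = dy at scattered pos
    im2col(dyp, Hout, Wout, Cout, kh, kw, stride, pad, H, W, dcols);
    const double* xp = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) xm(c, p) = xp[p + H * W * c];
    arma::mat dxm = M * dcols; // Cin x H*W
    double* dxp = dx.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) dxp[p + H * W * c] += dxm(c, p);
    dM += xm * dcols.t();
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Hout * Wout; ++p) db[o] += dyp[p + Hout * Wout * o];
  }
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  double* dwp = dw.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dwp[ki + kh * (kj + kw * (c + Cin * o))] =
            dM(c, ki + kh * (kj + kw * o));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Hout) * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  IntegerVector idx(y.size()); // flat index into x slab (per sample), 0-based
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * C;
    int* ip = idx.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * C;
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              const int fi = hi + H * (wi + W * c);
              if (xp[fi] > best) { best = xp[fi]; besti = fi; }
            }
          }
          const int oi = ho + Hout * (wo + Wout * c);
          yp[oi] = best; ip[oi] = besti;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector in_dim) {
  IntegerVector yd = dims4(dy);
  const int Hout = yd[0], Wout = yd[1], C = yd[2], N = yd[3];
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * C;
    const int* ip = idx.begin() + static_cast<R_xlen_t>(n) * Hout * Wout * C;
    double* dxp = dx.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (R_xlen_t p = 0; p < static_cast<R_xlen_t>(Hout) * Wout * C; ++p)
      if (ip[p] >= 0) dxp[ip[p]] += dyp[p];
  }
  return dx;
}

// Moving minimum over a win x win window, edge-replicated (separable).
// Window covers offsets [-(win-1)/2, win/2] so even windows are supported.
// [[Rcpp::export]]
NumericMatrix cpp_min_filter(NumericMatrix x, int win) {
  const int H = x.nrow(), W = x.ncol();
  const int lo = -((win - 1) / 2), hi = win / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) // vertical pass
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (int d = lo; d <= hi; ++d) {
        double v = x(clampi(i + d, 0, H - 1), j);
        if (v < m) m = v;
      }
      tmp(i, j) = m;
    }
  for (int j = 0; j < W; ++j) // horizontal pass
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (int d = lo; d <= hi; ++d) {
        double v = tmp(i, clampi(j + d, 0, W - 1));
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// Moving mean over win x win, edge-replicated (separable).
// [[Rcpp::export]]
NumericMatrix cpp_mean_filter(NumericMatrix x, int win) {
  const int H = x.nrow(), W = x.ncol();
  const int lo = -((win - 1) / 2), hi = win / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = lo; d <= hi; ++d) s += x(clampi(i + d, 0, H - 1), j);
      tmp(i, j) = s / win;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = lo; d <= hi; ++d) s += tmp(i, clampi(j + d, 0, W - 1));
      out(i, j) = s / win;
    }
  return out;
}

// 8-connected labeling of a logical/0-1 matrix; labels 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
      }
    }
  return lab;
}
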