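// Low-level kernels for the neural blocks: im2col/col2im convolution,
// max/average pooling with exact backward passes. Feature maps are stored as
// column-major R arrays with dim = (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// column matrix: (K*K*C) x (Ho*Wo*N); rows ordered (kh, kw, c) fastest-first
// to match the (H, W, C) storage order of the input.
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int K, int stride, int pad, int Ho, int Wo) {
  arma::mat col(K * K * C, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t colIdx = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        double* dst = col.colptr(colIdx);
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)c * H * W;
          for (int kw = 0; kw < K; ++kw) {
            int w = w0 + kw;
            for (int kh = 0; kh < K; ++kh) {
              int h = h0 + kh;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = xc[(size_t)w * H + h];
              dst[(size_t)c * K * K + (size_t)kw * K + kh] = v;
            }
          }
        }
      }
    }
  }
  return col;
}

static void col2im(const arma::mat& col, double* x, int H, int W, int C, int N,
                   int K, int stride, int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t colIdx = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        const double* src = col.colptr(colIdx);
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)c * H * W;
          for (int kw = 0; kw < K; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              xc[(size_t)w * H + h] += src[(size_t)c * K * K + (size_t)kw * K + kh];
            }
          }
        }
      }
    }
  }
}

// weight: array (K, K, Cin, Cout); bias: length Cout or NULL
// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  arma::mat col = im2col(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo);
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout, false, true);
  arma::mat out = wm.t() * col;                 // Cout x (Ho*Wo*N)
  if (bias.isNotNull()) {
    NumericVector b(bias);
    arma::vec bv(b.begin(), Cout, false, true);
    out.each_col() += bv;
  }
  // reorder Cout x (ho, wo, n) -> (ho, wo, cout, n)
  NumericVector res((size_t)Ho * Wo * Cout * N);
  double* r = res.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        r[(size_t)n * Ho * Wo * Cout + (size_t)c * Ho * Wo + p] =
          out(c, (size_t)n * Ho * Wo + p);
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return res;
}

// returns list(dx, dw, db)
// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  // gout (Ho,Wo,Cout,N) -> matrix Cout x (Ho*Wo*N)
  arma::mat gm(Cout, (size_t)Ho * Wo * N);
  const double* g = gout.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        gm(c, (size_t)n * Ho * Wo + p) =
          g[(size_t)n * Ho * Wo * Cout + (size_t)c * Ho * Wo + p];
  arma::mat col = im2col(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo);
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout, false, true);
  arma::mat dw = col * gm.t();                  // (K*K*Cin) x Cout
  arma::mat dcol = wm * gm;                     // (K*K*Cin) x (Ho*Wo*N)
  NumericVector dx((size_t)H * W * C * N);
  col2im(dcol, dx.begin(), H, W, C, N, K, stride, pad, Ho, Wo);
  dx.attr("dim") = xd;
  NumericVector dwv(dw.memptr(), dw.memptr() + dw.n_elem);
  dwv.attr("dim") = wd;
  List res = List::create(_["dx"] = dx, _["dw"] = dwv);
  if (has_bias) {
    arma::vec db = arma::sum(gm, 1);
    res["db"] = NumericVector(db.memptr(), db.memptr() + Cout);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < K; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              double v = xc[(size_t)w * H + h];
              if (v > best) { best = v; bi = (int)((size_t)w * H + h); }
            }
          }
          size_t oi = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          op[oi] = best;
          ap[oi] = bi;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector argmax, NumericVector gout,
                                   IntegerVector in_dim) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  NumericVector dx((size_t)H * W * C * N);
  double* d = dx.begin();
  const double* g = gout.begin();
  const int* a = argmax.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base_in = ((size_t)n * C + c) * H * W;
      size_t base_out = ((size_t)n * C + c) * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        if (a[base_out + p] >= 0) d[base_in + a[base_out + p]] += g[base_out + p];
    }
  dx.attr("dim") = in_dim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  double inv = 1.0 / (K * K);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < K; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              s += xc[(size_t)w * H + h];
            }
          }
          op[((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho] = s * inv;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(NumericVector gout, IntegerVector in_dim,
                                   int K, int stride, int pad) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  NumericVector dx((size_t)H * W * C * N);
  double* d = dx.begin();
  const double* g = gout.begin();
  double inv = 1.0 / (K * K);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = d + ((size_t)n * C + c) * H * W;
      size_t base_out = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double gv = g[base_out + (size_t)wo * Ho + ho] * inv;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < K; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              xc[(size_t)w * H + h] += gv;
            }
          }
        }
    }
  dx.attr("dim") = in_dim;
  return dx;
}
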