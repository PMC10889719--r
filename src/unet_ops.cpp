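// Minimal CNN kernels for the encoder-decoder segmentation network:
// 3x3 same-padding convolution, 2x2 max pooling and 2x2 stride-2 transposed
// convolution, each with forward and backward passes.
//
// Feature maps are 4-D R arrays dim = (H, W, C, N); conv weights (3,3,Cin,Cout);
// transposed-conv weights (2,2,Cin,Cout).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline size_t ix4(int h, int w, int c, int n, int H, int W, int C) {
  return (size_t)h + (size_t)H * (w + (size_t)W * (c + (size_t)C * n));
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(const NumericVector& x, const NumericVector& wgt,
                            const NumericVector& bias) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  IntegerVector dw = wgt.attr("dim");
  int Co = dw[3];
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* ybase = yp + ix4(0, 0, co, n, H, W, Co);
      double b = bias[co];
      for (size_t t = 0; t < (size_t)H * W; ++t) ybase[t] = b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xbase = xp + ix4(0, 0, ci, n, H, W, Ci);
        for (int dwi = 0; dwi < 3; ++dwi)
          for (int dhi = 0; dhi < 3; ++dhi) {
            double k = wp[(size_t)dhi + 3 * (dwi + 3 * ((size_t)ci + (size_t)Ci * co))];
            if (k == 0) continue;
            int oh = dhi - 1, ow = dwi - 1;
            int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
            int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
            for (int w = w0; w < w1; ++w) {
              double* yrow = ybase + (size_t)w * H;
              const double* xrow = xbase + (size_t)(w + ow) * H + oh;
              for (int h = h0; h < h1; ++h) yrow[h] += k * xrow[h];
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericVector& x, const NumericVector& wgt,
                   const NumericVector& dy) {
  IntegerVector dxd = x.attr("dim");
  int H = dxd[0], W = dxd[1], Ci = dxd[2], N = dxd[3];
  IntegerVector dwd = wgt.attr("dim");
  int Co = dwd[3];
  NumericVector dx((size_t)H * W * Ci * N), dw((size_t)9 * Ci * Co), db(Co);
  dx.attr("dim") = dxd;
  dw.attr("dim") = dwd;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double acc = 0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          acc += dy[ix4(h, w, co, n, H, W, Co)];
      db[co] += acc;
      const double* dybase = dy.begin() + ix4(0, 0, co, n, H, W, Co);
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xbase = x.begin() + ix4(0, 0, ci, n, H, W, Ci);
        double* dxbase = dx.begin() + ix4(0, 0, ci, n, H, W, Ci);
        for (int dwi = 0; dwi < 3; ++dwi)
          for (int dhi = 0; dhi < 3; ++dhi) {
            int oh = dhi - 1, ow = dwi - 1;
            int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
            int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
            double gw = 0;
            double k = wgt[(size_t)dhi + 3 * (dwi + 3 * ((size_t)ci + (size_t)Ci * co))];
            for (int w = w0; w < w1; ++w) {
              const double* dyrow = dybase + (size_t)w * H;
              const double* xrow = xbase + (size_t)(w + ow) * H + oh;
              double* dxrow = dxbase + (size_t)(w + ow) * H + oh;
              for (int h = h0; h < h1; ++h) {
                double g = dyrow[h];
                gw += g * xrow[h];
                dxrow[h] += k * g;
              }
            }
            dw[(size_t)dhi + 3 * (dwi + 3 * ((size_t)ci + (size_t)Ci * co))] += gw;
          }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1e300; size_t bidx = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              size_t t = ix4(2 * h + dh, 2 * w + dw, c, n, H, W, C);
              if (x[t] > best) { best = x[t]; bidx = t; }
            }
          size_t o = ix4(h, w, c, n, Ho, Wo, C);
          y[o] = best;
          arg[o] = (int)bidx + 1; // 1-based for R
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(const NumericVector& dy, const IntegerVector& arg,
                               const IntegerVector& in_dim) {
  size_t Nin = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(Nin);
  dx.attr("dim") = in_dim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[arg[t] - 1] += dy[t];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_tconv2_fwd(const NumericVector& x, const NumericVector& wgt,
                             const NumericVector& bias) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dw = wgt.attr("dim");
  int Co = dw[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          y[ix4(h, w, co, n, Ho, Wo, Co)] = bias[co];
      for (int ci = 0; ci < Ci; ++ci)
        for (int dwi = 0; dwi < 2; ++dwi)
          for (int dhi = 0; dhi < 2; ++dhi) {
            double k = wgt[(size_t)dhi + 2 * (dwi + 2 * ((size_t)ci + (size_t)Ci * co))];
            for (int w = 0; w < W; ++w)
              for (int h = 0; h < H; ++h)
                y[ix4(2 * h + dhi, 2 * w + dwi, co, n, Ho, Wo, Co)] +=
                  k * x[ix4(h, w, ci, n, H, W, Ci)];
          }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(const NumericVector& x, const NumericVector& wgt,
                    const NumericVector& dy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dwd = wgt.attr("dim");
  int Co = dwd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * Ci * N), dw((size_t)4 * Ci * Co), db(Co);
  dx.attr("dim") = d;
  dw.attr("dim") = dwd;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double acc = 0;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          acc += dy[ix4(h, w, co, n, Ho, Wo, Co)];
      db[co] += acc;
      for (int ci = 0; ci < Ci; ++ci)
        for (int dwi = 0; dwi < 2; ++dwi)
          for (int dhi = 0; dhi < 2; ++dhi) {
            double k = wgt[(size_t)dhi + 2 * (dwi + 2 * ((size_t)ci + (size_t)Ci * co))];
            double gw = 0;
            for (int w = 0; w < W; ++w)
              for (int h = 0; h < H; ++h) {
                double g = dy[ix4(2 * h + dhi, 2 * w + dwi, co, n, Ho, Wo, Co)];
                gw += g * x[ix4(h, w, ci, n, H, W, Ci)];
                dx[ix4(h, w, ci, n, H, W, Ci)] += k * g;
              }
            dw[(size_t)dhi + 2 * (dwi + 2 * ((size_t)ci + (size_t)Ci * co))] += gw;
          }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
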