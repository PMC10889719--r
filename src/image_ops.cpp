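// 2D image kernels: separable Gaussian blur, Sobel gradients, Canny edges,
// affine warping about the image centre, Harris corners, oriented patch
// descriptors and a brute-force bilateral filter.
//
// Images are R matrices indexed (row, col); coordinates use x = col, y = row.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur2d(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) { w[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += w[k + r]; }
  for (auto& v : w) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int k = -r; k <= r; ++k) acc += w[k + r] * img(reflect_idx(i + k, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int k = -r; k <= r; ++k) acc += w[k + r] * tmp(i, reflect_idx(j + k, nc));
      out(i, j) = acc;
    }
  return out;
}

// Sobel gradients; returns list(gx, gy) with x along columns.
// [[Rcpp::export]]
List cpp_sobel(const NumericMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double p[3][3];
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          p[a + 1][b + 1] = img(reflect_idx(i + a, nr), reflect_idx(j + b, nc));
      gx(i, j) = (p[0][2] + 2 * p[1][2] + p[2][2]) - (p[0][0] + 2 * p[1][0] + p[2][0]);
      gy(i, j) = (p[2][0] + 2 * p[2][1] + p[2][2]) - (p[0][0] + 2 * p[0][1] + p[0][2]);
    }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Canny edge detector with hysteresis thresholds on Sobel magnitude.
// Input image expected on a 0..255 scale.
// [[Rcpp::export]]
LogicalMatrix cpp_canny(const NumericMatrix& img, double t1, double t2, double sigma) {
  NumericMatrix sm = cpp_gauss_blur2d(img, sigma);
  List g = cpp_sobel(sm);
  NumericMatrix gx = g["gx"], gy = g["gy"];
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix mag(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      mag(i, j) = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
  // non-maximum suppression along quantized gradient direction
  LogicalMatrix strong(nr, nc), weak(nr, nc);
  double lo = std::min(t1, t2), hi = std::max(t1, t2);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = mag(i, j);
      if (m < lo) continue;
      double ang = std::atan2(gy(i, j), gx(i, j));
      double deg = ang * 180.0 / M_PI;
      if (deg < 0) deg += 180.0;
      int di = 0, dj = 0;
      if (deg < 22.5 || deg >= 157.5) { di = 0; dj = 1; }
      else if (deg < 67.5) { di = 1; dj = 1; }
      else if (deg < 112.5) { di = 1; dj = 0; }
      else { di = 1; dj = -1; }
      double m1 = mag(reflect_idx(i + di, nr), reflect_idx(j + dj, nc));
      double m2 = mag(reflect_idx(i - di, nr), reflect_idx(j - dj, nc));
      if (m >= m1 && m >= m2) {
        if (m >= hi) strong(i, j) = true; else weak(i, j) = true;
      }
    }
  // hysteresis: keep weak edges connected to strong ones
  LogicalMatrix out(nr, nc);
  std::queue<std::pair<int,int>> q;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (strong(i, j)) { out(i, j) = true; q.push({i, j}); }
  while (!q.empty()) {
    auto [i, j] = q.front(); q.pop();
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        int ii = i + a, jj = j + b;
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (weak(ii, jj) && !out(ii, jj)) { out(ii, jj) = true; q.push({ii, jj}); }
      }
  }
  return out;
}

// Affine warp: out(p) = img(A^{-1} p) with A = T(tx,ty) . R(theta) . S(s)
// acting about the image centre; theta in degrees, bilinear or nearest.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, double tx, double ty,
                              double theta_deg, double s,
                              const std::string& interp, double background) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  bool nearest = (interp == "nearest");
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      // inverse map: q = R(-theta) (p - c - t)/s + c
      double px = j - cx - tx, py = i - cy - ty;
      double qx = ( ct * px + st * py) / s + cx;
      double qy = (-st * px + ct * py) / s + cy;
      if (nearest) {
        int xi = (int)std::lround(qx), yi = (int)std::lround(qy);
        out(i, j) = (xi < 0 || yi < 0 || xi >= nc || yi >= nr) ? background : img(yi, xi);
      } else {
        if (qx < 0 || qy < 0 || qx > nc - 1 || qy > nr - 1) {
          out(i, j) = background;
        } else {
          int x0 = std::min((int)std::floor(qx), nc - 1);
          int y0 = std::min((int)std::floor(qy), nr - 1);
          int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
          double fx = qx - x0, fy = qy - y0;
          out(i, j) = img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy)
                    + img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
        }
      }
    }
  }
  return out;
}

// Warp into a differently-sized target frame.  The transform maps moving
// coordinates to target coordinates about the moving image's centre
// (cx, cy, 0-based): q = c + R(-theta) (p - c - t) / s for target pixel p.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine_frame(const NumericMatrix& img, int nrow_out,
                                    int ncol_out, double tx, double ty,
                                    double theta_deg, double s,
                                    const std::string& interp, double background) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nrow_out, ncol_out);
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  bool nearest = (interp == "nearest");
  for (int i = 0; i < nrow_out; ++i) {
    for (int j = 0; j < ncol_out; ++j) {
      double px = j - cx - tx, py = i - cy - ty;
      double qx = ( ct * px + st * py) / s + cx;
      double qy = (-st * px + ct * py) / s + cy;
      if (nearest) {
        int xi = (int)std::lround(qx), yi = (int)std::lround(qy);
        out(i, j) = (xi < 0 || yi < 0 || xi >= nc || yi >= nr) ? background : img(yi, xi);
      } else if (qx < 0 || qy < 0 || qx > nc - 1 || qy > nr - 1) {
        out(i, j) = background;
      } else {
        int x0 = std::min((int)std::floor(qx), nc - 1);
        int y0 = std::min((int)std::floor(qy), nr - 1);
        int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
        double fx = qx - x0, fy = qy - y0;
        out(i, j) = img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy)
                  + img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
      }
    }
  }
  return out;
}

// Harris corner response on a blurred image.
// [[Rcpp::export]]
NumericMatrix cpp_harris(const NumericMatrix& img, double sigma_d, double sigma_i, double k) {
  NumericMatrix sm = cpp_gauss_blur2d(img, sigma_d);
  List g = cpp_sobel(sm);
  NumericMatrix gx = g["gx"], gy = g["gy"];
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix xx(nr, nc), yy(nr, nc), xy(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      xx(i, j) = gx(i, j) * gx(i, j);
      yy(i, j) = gy(i, j) * gy(i, j);
      xy(i, j) = gx(i, j) * gy(i, j);
    }
  xx = cpp_gauss_blur2d(xx, sigma_i);
  yy = cpp_gauss_blur2d(yy, sigma_i);
  xy = cpp_gauss_blur2d(xy, sigma_i);
  NumericMatrix resp(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double det = xx(i, j) * yy(i, j) - xy(i, j) * xy(i, j);
      double tr = xx(i, j) + yy(i, j);
      resp(i, j) = det - k * tr * tr;
    }
  return resp;
}

// Sample oriented, normalized patch descriptors.  pts: n x 3 (x, y, theta_rad),
// 0-based coordinates.  Descriptor: grid x grid samples spaced `spacing` px in
// the rotated frame, bilinear, zero-mean unit-variance normalized.
// [[Rcpp::export]]
NumericMatrix cpp_patch_descriptors(const NumericMatrix& img, const NumericMatrix& pts,
                                    int grid, double spacing) {
  int n = pts.nrow(), nr = img.nrow(), nc = img.ncol();
  int d = grid * grid;
  NumericMatrix out(n, d);
  double half = (grid - 1) / 2.0;
  for (int p = 0; p < n; ++p) {
    double x0 = pts(p, 0), y0 = pts(p, 1), th = pts(p, 2);
    double ct = std::cos(th), st = std::sin(th);
    int idx = 0;
    double mean = 0;
    std::vector<double> vals(d);
    for (int a = 0; a < grid; ++a) {
      for (int b = 0; b < grid; ++b) {
        double u = (b - half) * spacing, v = (a - half) * spacing;
        double qx = x0 + ct * u - st * v;
        double qy = y0 + st * u + ct * v;
        double val = 0;
        int xi = (int)std::floor(qx), yi = (int)std::floor(qy);
        if (xi >= 0 && yi >= 0 && xi + 1 < nc && yi + 1 < nr) {
          double fx = qx - xi, fy = qy - yi;
          val = img(yi, xi) * (1 - fx) * (1 - fy) + img(yi, xi + 1) * fx * (1 - fy)
              + img(yi + 1, xi) * (1 - fx) * fy + img(yi + 1, xi + 1) * fx * fy;
        }
        vals[idx++] = val;
        mean += val;
      }
    }
    mean /= d;
    double ss = 0;
    for (int k = 0; k < d; ++k) { vals[k] -= mean; ss += vals[k] * vals[k]; }
    double norm = std::sqrt(ss);
    if (norm < 1e-12) norm = 1;
    for (int k = 0; k < d; ++k) out(p, k) = vals[k] / norm;
  }
  return out;
}

static inline double cubic_kernel(double t) {
  // Catmull-Rom (a = -0.5)
  t = std::fabs(t);
  if (t < 1) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// Resize with nearest / bilinear / bicubic (Catmull-Rom) sampling.
// [[Rcpp::export]]
NumericMatrix cpp_resize(const NumericMatrix& img, int nrow_out, int ncol_out,
                         const std::string& method) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nrow_out, ncol_out);
  double sy = (double)nr / nrow_out, sx = (double)nc / ncol_out;
  for (int i = 0; i < nrow_out; ++i) {
    double qy = (i + 0.5) * sy - 0.5;
    for (int j = 0; j < ncol_out; ++j) {
      double qx = (j + 0.5) * sx - 0.5;
      if (method == "nearest") {
        int yi = std::min(std::max((int)std::lround(qy), 0), nr - 1);
        int xi = std::min(std::max((int)std::lround(qx), 0), nc - 1);
        out(i, j) = img(yi, xi);
      } else if (method == "bilinear") {
        int y0 = (int)std::floor(qy), x0 = (int)std::floor(qx);
        double fy = qy - y0, fx = qx - x0;
        int y1 = std::min(std::max(y0 + 1, 0), nr - 1), x1 = std::min(std::max(x0 + 1, 0), nc - 1);
        y0 = std::min(std::max(y0, 0), nr - 1); x0 = std::min(std::max(x0, 0), nc - 1);
        out(i, j) = img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy)
                  + img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
      } else { // bicubic
        int y0 = (int)std::floor(qy), x0 = (int)std::floor(qx);
        double acc = 0, wacc = 0;
        for (int a = -1; a <= 2; ++a) {
          int yi = std::min(std::max(y0 + a, 0), nr - 1);
          double wy = cubic_kernel(qy - (y0 + a));
          for (int b = -1; b <= 2; ++b) {
            int xi = std::min(std::max(x0 + b, 0), nc - 1);
            double w = wy * cubic_kernel(qx - (x0 + b));
            acc += w * img(yi, xi); wacc += w;
          }
        }
        out(i, j) = wacc != 0 ? acc / wacc : 0.0;
      }
    }
  }
  return out;
}

// Brute-force bilateral filter; sigma_color on the same scale as the values.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(const NumericMatrix& img, int radius,
                            double sigma_color, double sigma_space) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double ic2 = 1.0 / (2.0 * sigma_color * sigma_color);
  double is2 = 1.0 / (2.0 * sigma_space * sigma_space);
  std::vector<double> sw((2 * radius + 1) * (2 * radius + 1));
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      sw[(a + radius) * (2 * radius + 1) + (b + radius)] = std::exp(-(a * a + b * b) * is2);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double c = img(i, j), acc = 0, wacc = 0;
      for (int a = -radius; a <= radius; ++a) {
        int ii = i + a;
        if (ii < 0 || ii >= nr) continue;
        for (int b = -radius; b <= radius; ++b) {
          int jj = j + b;
          if (jj < 0 || jj >= nc) continue;
          double v = img(ii, jj);
          double w = sw[(a + radius) * (2 * radius + 1) + (b + radius)]
                   * std::exp(-(v - c) * (v - c) * ic2);
          acc += w * v; wacc += w;
        }
      }
      out(i, j) = acc / wacc;
    }
  }
  return out;
}
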