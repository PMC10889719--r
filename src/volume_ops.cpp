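// 3D volume kernels: separable Gaussian blur, exact squared Euclidean
// distance transform (Felzenszwalb--Huttenlocher), connected-component
// labelling (6/26), local maximal-sphere thickness, oblique plane sampling.
//
// Volumes are R arrays dim = (n1, n2, n3); linear index i + n1*(j + n2*k).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// half-sample symmetric reflection (edge duplicated): the induced smoothing
// matrix is symmetric and doubly stochastic, so Gaussian blur conserves the
// volume mean exactly.
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - 1 - i; }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(const NumericVector& vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  if (sigma <= 0) { NumericVector out = clone(vol); return out; }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) { w[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += w[k + r]; }
  for (auto& v : w) v /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto idx = [&](int i, int j, int k) { return (size_t)i + (size_t)n1 * (j + (size_t)n2 * k); };
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) acc += w[t + r] * a[idx(refl(i + t, n1), j, k)];
        b[idx(i, j, k)] = acc;
      }
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i)
      for (int j = 0; j < n2; ++j) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) acc += w[t + r] * b[idx(i, refl(j + t, n2), k)];
        a[idx(i, j, k)] = acc;
      }
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i)
      for (int k = 0; k < n3; ++k) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) acc += w[t + r] * a[idx(i, j, refl(k + t, n3))];
        b[idx(i, j, k)] = acc;
      }
  NumericVector out(vol.size());
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = d;
  return out;
}

// 1-D squared distance transform (lower envelope of parabolas)
static void dt1d(const std::vector<double>& f, std::vector<double>& d_out) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sP;
    while (true) {
      sP = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (sP <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sP; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d_out[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from each true voxel to the nearest
// false voxel.  Border is NOT treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(const LogicalVector& fg) {
  IntegerVector d = fg.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  size_t N = (size_t)n1 * n2 * n3;
  const double INF = 1e18;
  std::vector<double> a(N);
  for (size_t t = 0; t < N; ++t) a[t] = fg[t] ? INF : 0.0;
  auto idx = [&](int i, int j, int k) { return (size_t)i + (size_t)n1 * (j + (size_t)n2 * k); };
  std::vector<double> f(std::max({n1, n2, n3})), g(std::max({n1, n2, n3}));
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) f[i] = a[idx(i, j, k)];
      f.resize(n1); g.resize(n1); dt1d(f, g);
      for (int i = 0; i < n1; ++i) a[idx(i, j, k)] = g[i];
    }
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      f.resize(n2); g.resize(n2);
      for (int j = 0; j < n2; ++j) f[j] = a[idx(i, j, k)];
      dt1d(f, g);
      for (int j = 0; j < n2; ++j) a[idx(i, j, k)] = g[j];
    }
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      f.resize(n3); g.resize(n3);
      for (int k = 0; k < n3; ++k) f[k] = a[idx(i, j, k)];
      dt1d(f, g);
      for (int k = 0; k < n3; ++k) a[idx(i, j, k)] = g[k];
    }
  NumericVector out(N);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = d;
  return out;
}

// Connected-component labelling, connectivity 6 or 26; labels from 1.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& fg, int connectivity) {
  IntegerVector d = fg.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  size_t N = (size_t)n1 * n2 * n3;
  IntegerVector lab(N);
  lab.attr("dim") = d;
  std::vector<std::array<int,3>> nb;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        nb.push_back({a, b, c});
      }
  auto idx = [&](int i, int j, int k) { return (size_t)i + (size_t)n1 * (j + (size_t)n2 * k); };
  int cur = 0;
  std::vector<size_t> stack;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        size_t t = idx(i, j, k);
        if (!fg[t] || lab[t]) continue;
        ++cur;
        lab[t] = cur;
        stack.clear(); stack.push_back(t);
        while (!stack.empty()) {
          size_t u = stack.back(); stack.pop_back();
          int ui = u % n1, uj = (u / n1) % n2, uk = u / ((size_t)n1 * n2);
          for (auto& s : nb) {
            int vi = ui + s[0], vj = uj + s[1], vk = uk + s[2];
            if (vi < 0 || vj < 0 || vk < 0 || vi >= n1 || vj >= n2 || vk >= n3) continue;
            size_t v = idx(vi, vj, vk);
            if (fg[v] && !lab[v]) { lab[v] = cur; stack.push_back(v); }
          }
        }
      }
  return lab;
}

// Local thickness (maximal-sphere): for each foreground voxel, the diameter of
// the largest inscribed sphere containing it.  edt_sq is cpp_edt3d_sq(fg).
// Voxels are painted from the largest inscribed radius downwards.
// rmax caps the painted sphere radius (the caller's mirror-padding horizon);
// thickness saturates at 2*rmax - 1 in regions wider than the horizon.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(const LogicalVector& fg, const NumericVector& edt_sq,
                                  double rmax) {
  IntegerVector d = fg.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  size_t N = (size_t)n1 * n2 * n3;
  // Keep only non-dominated sphere centres: voxel p is dropped when a
  // neighbour q satisfies r_q >= r_p + |p - q|, i.e. p's inscribed ball lies
  // entirely inside q's.  Chains of domination end at a kept centre whose
  // ball contains every dropped ball, so coverage is exact.
  std::vector<size_t> ord;
  ord.reserve(N / 8);
  for (size_t t = 0; t < N; ++t) {
    if (!fg[t]) continue;
    double rp = std::sqrt(edt_sq[t]);
    if (rp >= rmax) continue;  // saturated centres are handled by the caller
    int ci = t % n1, cj = (t / n1) % n2, ck = t / ((size_t)n1 * n2);
    bool dominated = false;
    for (int a = -1; a <= 1 && !dominated; ++a)
      for (int b = -1; b <= 1 && !dominated; ++b)
        for (int c = -1; c <= 1 && !dominated; ++c) {
          if (!a && !b && !c) continue;
          int i = ci + a, j = cj + b, k = ck + c;
          if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) continue;
          size_t u = (size_t)i + (size_t)n1 * (j + (size_t)n2 * k);
          if (!fg[u]) continue;
          double dq = std::sqrt((double)(a * a + b * b + c * c));
          if (std::sqrt(edt_sq[u]) >= rp + dq - 1e-12) dominated = true;
        }
    if (!dominated) ord.push_back(t);
  }
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return edt_sq[a] > edt_sq[b]; });
  NumericVector th(N);
  th.attr("dim") = d;
  for (size_t o = 0; o < ord.size(); ++o) {
    size_t t = ord[o];
    double r = std::sqrt(edt_sq[t]);
    double r2 = r * r;
    // EDT measures centre-to-centre distance; the inscribed ball touches the
    // phase boundary half a voxel earlier on each side.
    double diam = 2.0 * r - 1.0;
    int ci = t % n1, cj = (t / n1) % n2, ck = t / ((size_t)n1 * n2);
    int ri = (int)std::floor(r);
    for (int a = -ri; a <= ri; ++a) {
      int i = ci + a; if (i < 0 || i >= n1) continue;
      for (int b = -ri; b <= ri; ++b) {
        int j = cj + b; if (j < 0 || j >= n2) continue;
        double rem = r2 - a * a - b * b;
        if (rem < 0) continue;
        int rc = (int)std::floor(std::sqrt(rem));
        for (int c = -rc; c <= rc; ++c) {
          int k = ck + c; if (k < 0 || k >= n3) continue;
          size_t u = (size_t)i + (size_t)n1 * (j + (size_t)n2 * k);
          if (th[u] < diam) th[u] = diam;
        }
      }
    }
  }
  return th;
}

// Trilinear sampling of an oblique plane.  origin: 0-based voxel coords of the
// output pixel (0,0); u, v: in-plane step vectors (voxel units per output px).
// Out-of-volume samples take `background`.
// [[Rcpp::export]]
NumericMatrix cpp_sample_plane(const NumericVector& vol,
                               const NumericVector& origin,
                               const NumericVector& u, const NumericVector& v,
                               int nrow_out, int ncol_out, double background) {
  IntegerVector d = vol.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  auto idx = [&](int i, int j, int k) { return (size_t)i + (size_t)n1 * (j + (size_t)n2 * k); };
  NumericMatrix out(nrow_out, ncol_out);
  for (int r = 0; r < nrow_out; ++r) {
    for (int c = 0; c < ncol_out; ++c) {
      double p1 = origin[0] + r * v[0] + c * u[0];
      double p2 = origin[1] + r * v[1] + c * u[1];
      double p3 = origin[2] + r * v[2] + c * u[2];
      int i0 = (int)std::floor(p1), j0 = (int)std::floor(p2), k0 = (int)std::floor(p3);
      if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= n1 || j0 + 1 >= n2 || k0 + 1 >= n3) {
        // clamp exact upper-boundary hits
        if (p1 >= 0 && p2 >= 0 && p3 >= 0 &&
            p1 <= n1 - 1 && p2 <= n2 - 1 && p3 <= n3 - 1) {
          int ii = std::min(i0, n1 - 1), jj = std::min(j0, n2 - 1), kk = std::min(k0, n3 - 1);
          out(r, c) = vol[idx(ii, jj, kk)];
        } else out(r, c) = background;
        continue;
      }
      double f1 = p1 - i0, f2 = p2 - j0, f3 = p3 - k0;
      double acc = 0;
      for (int a = 0; a <= 1; ++a)
        for (int b = 0; b <= 1; ++b)
          for (int cc = 0; cc <= 1; ++cc) {
            double w = (a ? f1 : 1 - f1) * (b ? f2 : 1 - f2) * (cc ? f3 : 1 - f3);
            acc += w * vol[idx(i0 + a, j0 + b, k0 + cc)];
          }
      out(r, c) = acc;
    }
  }
  return out;
}
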