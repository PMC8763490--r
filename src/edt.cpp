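#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include "edt.h"

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable squared-distance lower envelope, anisotropic voxel spacing.
// Empty sites carry a large finite squared distance so the envelope
// arithmetic stays well defined; an all-empty mask yields huge values that
// the R wrapper turns into an error.

static const double BIG = 1e30;
static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform with sample spacing `h`.
// Envelope sentinels use true infinities (comparison only); empty sites use
// the large finite BIG so the envelope arithmetic never produces NaN.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

void edt_raw(const unsigned char* mask, int H, int W, double sy, double sx,
             double* out) {
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  std::vector<double> tmp(static_cast<size_t>(H) * W);

  for (int j = 0; j < W; ++j) {            // pass 1: within columns, spacing sy
    for (int i = 0; i < H; ++i) {
      f[i] = mask[i + static_cast<size_t>(j) * H] ? 0.0 : BIG;
    }
    dt1d(f, d, H, sy);
    for (int i = 0; i < H; ++i) tmp[i + static_cast<size_t>(j) * H] = d[i];
  }
  for (int i = 0; i < H; ++i) {            // pass 2: within rows, spacing sx
    for (int j = 0; j < W; ++j) f[j] = tmp[i + static_cast<size_t>(j) * H];
    dt1d(f, d, W, sx);
    for (int j = 0; j < W; ++j) {
      out[i + static_cast<size_t>(j) * H] = std::sqrt(d[j]);
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericMatrix edt_cpp(Rcpp::LogicalMatrix mask, double sy, double sx) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> m(static_cast<size_t>(H) * W);
  for (size_t t = 0; t < m.size(); ++t) m[t] = mask[t] ? 1 : 0;
  Rcpp::NumericMatrix out(H, W);
  edt_raw(m.data(), H, W, sy, sx, REAL(out));
  return out;
}

// Connected-component labelling (BFS) for 2D (8-connectivity) or 3D
// (26-connectivity) masks. Returns integer labels, 0 = background.
// [[Rcpp::export]]
Rcpp::IntegerVector label_components_cpp(Rcpp::LogicalVector mask,
                                         Rcpp::IntegerVector dims) {
  const int H = dims[0], W = dims[1], D = dims.size() > 2 ? dims[2] : 1;
  const size_t n = static_cast<size_t>(H) * W * D;
  Rcpp::IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int k = p / (static_cast<size_t>(H) * W);
      int rem = p - static_cast<size_t>(k) * H * W;
      int j = rem / H, i = rem % H;
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W || kk < 0 || kk >= D) {
              continue;
            }
            size_t q = ii + static_cast<size_t>(jj) * H +
                       static_cast<size_t>(kk) * H * W;
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
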