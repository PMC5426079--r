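#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// MST region-merging segmentation
//
// Pixels are graph vertices; edges join spatially neighbouring pixels with
// weight |I_a - I_b|.  Edges are visited in non-descending weight order
// (stable: ties keep construction order, which is row-major with the
// right-edge emitted before the down-edge) and two distinct regions are
// merged when the inter-region mean difference does not exceed the smaller
// internal tolerance sigma(C) + tau(C), tau(C) = (k/|C|) * (1 + beta/alpha),
// beta = mu/sigma (0 when sigma = 0).
// ---------------------------------------------------------------------------

struct DSU {
  std::vector<int> parent;
  std::vector<double> n, s, ss; // size, sum, sum of squares, kept at roots
  explicit DSU(int m) : parent(m), n(m, 1.0), s(m), ss(m) {
    for (int i = 0; i < m; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) { // a, b roots
    if (n[a] < n[b]) std::swap(a, b);
    parent[b] = a;
    n[a] += n[b];
    s[a] += s[b];
    ss[a] += ss[b];
  }
};

static inline double region_sd(double n, double s, double ss) {
  double v = ss / n - (s / n) * (s / n);
  return v > 0 ? std::sqrt(v) : 0.0;
}

static inline double tau_of(double n, double s, double ss, double k,
                            double alpha) {
  double sd = region_sd(n, s, ss);
  double beta = sd > 0 ? (s / n) / sd : 0.0;
  return (k / n) * (1.0 + beta / alpha);
}

// [[Rcpp::export]]
List cpp_segment(NumericMatrix img, double k, double alpha,
                 int connectivity) {
  const int H = img.nrow(), W = img.ncol(), N = H * W;
  // pixel linear index: column-major (R convention), 0-based internally
  auto idx = [H](int r, int c) { return r + c * H; };

  // edges in construction order: row-major pixel scan; per pixel emit
  // right, down, then (8-connectivity) down-right, down-left
  std::vector<int> ea, eb;
  std::vector<double> ew;
  ea.reserve(2 * N);
  eb.reserve(2 * N);
  ew.reserve(2 * N);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double v = img(r, c);
      if (c + 1 < W) {
        ea.push_back(idx(r, c));
        eb.push_back(idx(r, c + 1));
        ew.push_back(std::fabs(v - img(r, c + 1)));
      }
      if (r + 1 < H) {
        ea.push_back(idx(r, c));
        eb.push_back(idx(r + 1, c));
        ew.push_back(std::fabs(v - img(r + 1, c)));
      }
      if (connectivity == 8) {
        if (r + 1 < H && c + 1 < W) {
          ea.push_back(idx(r, c));
          eb.push_back(idx(r + 1, c + 1));
          ew.push_back(std::fabs(v - img(r + 1, c + 1)));
        }
        if (r + 1 < H && c >= 1) {
          ea.push_back(idx(r, c));
          eb.push_back(idx(r + 1, c - 1));
          ew.push_back(std::fabs(v - img(r + 1, c - 1)));
        }
      }
    }
  }
  const int M = static_cast<int>(ew.size());
  std::vector<int> ord(M);
  for (int i = 0; i < M; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&ew](int i, int j) { return ew[i] < ew[j]; });

  DSU dsu(N);
  for (int q = 0; q < N; ++q) {
    double v = img[q]; // column-major linear access matches idx()
    dsu.s[q] = v;
    dsu.ss[q] = v * v;
  }
  for (int q = 0; q < M; ++q) {
    int e = ord[q];
    int ra = dsu.find(ea[e]), rb = dsu.find(eb[e]);
    if (ra == rb) continue;
    double mu_a = dsu.s[ra] / dsu.n[ra], mu_b = dsu.s[rb] / dsu.n[rb];
    double dif = std::fabs(mu_a - mu_b);
    double ia = region_sd(dsu.n[ra], dsu.s[ra], dsu.ss[ra]) +
                tau_of(dsu.n[ra], dsu.s[ra], dsu.ss[ra], k, alpha);
    double ib = region_sd(dsu.n[rb], dsu.s[rb], dsu.ss[rb]) +
                tau_of(dsu.n[rb], dsu.s[rb], dsu.ss[rb], k, alpha);
    if (dif <= std::min(ia, ib)) dsu.unite(ra, rb);
  }

  // compact labels, numbered by first appearance in column-major scan
  IntegerMatrix labels(H, W);
  std::vector<int> lab(N, 0);
  int nlab = 0;
  for (int q = 0; q < N; ++q) {
    int r = dsu.find(q);
    if (lab[r] == 0) lab[r] = ++nlab;
    labels[q] = lab[r];
  }
  NumericVector size(nlab), sum(nlab), sumsq(nlab);
  for (int q = 0; q < N; ++q) {
    int r = dsu.find(q);
    if (q == r) {
      int l = lab[r] - 1;
      size[l] = dsu.n[r];
      sum[l] = dsu.s[r];
      sumsq[l] = dsu.ss[r];
    }
  }
  return List::create(_["labels"] = labels, _["size"] = size,
                      _["sum"] = sum, _["sumsq"] = sumsq);
}

// ---------------------------------------------------------------------------
// Bilateral filter: Gaussian spatial x Gaussian range weights, window of
// (odd) diameter d, replicate-free normalisation (window clipped at border).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, int d, double sigma_color,
                            double sigma_space) {
  const int H = img.nrow(), W = img.ncol();
  const int rad = d / 2;
  const double cs = -0.5 / (sigma_space * sigma_space);
  const double cc = -0.5 / (sigma_color * sigma_color);
  std::vector<double> spw((2 * rad + 1) * (2 * rad + 1));
  for (int dy = -rad; dy <= rad; ++dy)
    for (int dx = -rad; dx <= rad; ++dx)
      spw[(dy + rad) * (2 * rad + 1) + (dx + rad)] =
          std::exp(cs * (dx * dx + dy * dy));
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double v0 = img(r, c), acc = 0.0, wsum = 0.0;
      int r0 = std::max(0, r - rad), r1 = std::min(H - 1, r + rad);
      int c0 = std::max(0, c - rad), c1 = std::min(W - 1, c + rad);
      for (int cc2 = c0; cc2 <= c1; ++cc2) {
        for (int rr = r0; rr <= r1; ++rr) {
          double v = img(rr, cc2);
          double w = spw[(rr - r + rad) * (2 * rad + 1) + (cc2 - c + rad)] *
                     std::exp(cc * (v - v0) * (v - v0));
          acc += w * v;
          wsum += w;
        }
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean shift filtering over the joint spatial-range domain.  Each pixel's
// mode search starts at its own position with range value init(r, c);
// the window is the disc of radius sp restricted to pixels within sr of the
// current range value.  The converged mode intensity is returned.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_meanshift(NumericMatrix img, NumericMatrix init, int sp,
                            double sr, int max_iter) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double x = c, y = r, v = init(r, c);
      for (int it = 0; it < max_iter; ++it) {
        int r0 = std::max(0, (int)std::floor(y) - sp);
        int r1 = std::min(H - 1, (int)std::ceil(y) + sp);
        int c0 = std::max(0, (int)std::floor(x) - sp);
        int c1 = std::min(W - 1, (int)std::ceil(x) + sp);
        double sx = 0, sy = 0, sv = 0, n = 0;
        for (int cc = c0; cc <= c1; ++cc) {
          for (int rr = r0; rr <= r1; ++rr) {
            double dx = cc - x, dy = rr - y;
            if (dx * dx + dy * dy > (double)sp * sp) continue;
            double u = img(rr, cc);
            if (std::fabs(u - v) > sr) continue;
            sx += cc;
            sy += rr;
            sv += u;
            n += 1;
          }
        }
        if (n == 0) {
          // seed value (e.g. from a coarser pyramid level) matches nothing
          // here: restart the search from the pixel's own value
          if (it == 0 && v != img(r, c)) {
            v = img(r, c);
            continue;
          }
          break;
        }
        double nx = sx / n, ny = sy / n, nv = sv / n;
        double moved = std::fabs(nx - x) + std::fabs(ny - y) +
                       std::fabs(nv - v);
        x = nx;
        y = ny;
        v = nv;
        if (moved < 0.5) break;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sobel gradient magnitude with replicate border padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sobel(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  auto at = [&](int r, int c) -> double {
    r = std::min(std::max(r, 0), H - 1);
    c = std::min(std::max(c, 0), W - 1);
    return img(r, c);
  };
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double gx = -at(r - 1, c - 1) - 2 * at(r, c - 1) - at(r + 1, c - 1) +
                  at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1);
      double gy = -at(r - 1, c - 1) - 2 * at(r - 1, c) - at(r - 1, c + 1) +
                  at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1);
      out(r, c) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, replicate padding, kernel radius ceil(3 sigma).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += ker[i + rad];
  }
  for (auto &k : ker) k /= ksum;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = std::min(std::max(r + i, 0), H - 1);
        acc += ker[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = std::min(std::max(c + i, 0), W - 1);
        acc += ker[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}
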