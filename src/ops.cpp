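#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Horizontal running-min/max (monotonic deque) over a window of half-width w.
// Writes result for one row into out.
static void run_extreme(const double* row, int n, int w, bool want_min,
                        double* out) {
  std::deque<int> q;
  int j = 0;
  for (int i = 0; i < n; ++i) {
    // push entering index i + w
    for (; j <= i + w && j < n; ++j) {
      while (!q.empty() &&
             (want_min ? row[q.back()] >= row[j] : row[q.back()] <= row[j]))
        q.pop_back();
      q.push_back(j);
    }
    while (q.front() < i - w) q.pop_front();
    out[i] = row[q.front()];
  }
}

// Grayscale erosion/dilation with an exact Euclidean disk of the given
// radius, decomposed into per-row chords; O(H * W * (2r+1)).
static NumericMatrix disk_extreme(const NumericMatrix& img, double radius,
                                  bool want_min) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::floor(radius);
  NumericMatrix out(H, W);
  const double init = want_min ? std::numeric_limits<double>::infinity()
                               : -std::numeric_limits<double>::infinity();
  std::vector<double> rowbuf(W), filt(W);
  // chord half-widths per vertical offset
  std::vector<int> hw(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy) {
    double s = radius * radius - (double)dy * dy;
    hw[dy + r] = s >= 0 ? (int)std::floor(std::sqrt(s) + 1e-9) : -1;
  }
  for (int i = 0; i < H; ++i) {
    for (int x = 0; x < W; ++x) out(i, x) = init;
    for (int dy = -r; dy <= r; ++dy) {
      int y = i + dy;
      if (y < 0 || y >= H || hw[dy + r] < 0) continue;
      for (int x = 0; x < W; ++x) rowbuf[x] = img(y, x);
      run_extreme(rowbuf.data(), W, hw[dy + r], want_min, filt.data());
      if (want_min) {
        for (int x = 0; x < W; ++x)
          if (filt[x] < out(i, x)) out(i, x) = filt[x];
      } else {
        for (int x = 0; x < W; ++x)
          if (filt[x] > out(i, x)) out(i, x) = filt[x];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode_disk(NumericMatrix img, double radius) {
  return disk_extreme(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate_disk(NumericMatrix img, double radius) {
  return disk_extreme(img, radius, false);
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const double* f, int n, double* d, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest true pixel.
// [[Rcpp::export]]
NumericMatrix cpp_sq_edt(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(H, W);
  int n = std::max(H, W);
  std::vector<double> f(n), out(n), z(n + 1);
  std::vector<int> v(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f.data(), H, out.data(), v.data(), z.data());
    for (int i = 0; i < H; ++i) d(i, j) = out[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d(i, j);
    dt1d(f.data(), W, out.data(), v.data(), z.data());
    for (int j = 0; j < W; ++j) d(i, j) = out[j];
  }
  return d;
}

// Separable Gaussian blur, replicate boundary, kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int i = 0; i < H; ++i)  // horizontal pass
    for (int j = 0; j < W; ++j) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        acc += k[t + r] * img(i, jj);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)  // vertical pass
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        acc += k[t + r] * tmp(ii, j);
      }
      out(i, j) = acc;
    }
  return out;
}

// Scale-normalized negative LoG response: -sigma^2 * Laplacian(G_sigma * I),
// so bright blobs give positive maxima. Replicate boundary Laplacian.
// [[Rcpp::export]]
NumericMatrix cpp_norm_log(NumericMatrix img, double sigma) {
  NumericMatrix g = cpp_gaussian_blur(img, sigma);
  const int H = g.nrow(), W = g.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double up = g(i > 0 ? i - 1 : 0, j);
      double dn = g(i < H - 1 ? i + 1 : H - 1, j);
      double lf = g(i, j > 0 ? j - 1 : 0);
      double rt = g(i, j < W - 1 ? j + 1 : W - 1);
      out(i, j) = -sigma * sigma * (up + dn + lf + rt - 4.0 * g(i, j));
    }
  return out;
}

// Local maxima of a H x W x S response stack (vector in column-major order):
// points >= all 26 neighbours and > threshold. Returns matrix with columns
// row, col, scale-index (1-based), response.
// [[Rcpp::export]]
NumericMatrix cpp_stack_maxima(NumericVector stack, int H, int W, int S,
                               double threshold) {
  std::vector<double> rows, cols, scales, vals;
  auto at = [&](int i, int j, int s) { return stack[i + (long)H * j + (long)H * W * s]; };
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = at(i, j, s);
        if (!(v > threshold)) continue;
        bool ok = true;
        for (int ds = -1; ds <= 1 && ok; ++ds)
          for (int dj = -1; dj <= 1 && ok; ++dj)
            for (int di = -1; di <= 1 && ok; ++di) {
              if (!di && !dj && !ds) continue;
              int ii = i + di, jj = j + dj, ss = s + ds;
              if (ii < 0 || ii >= H || jj < 0 || jj >= W || ss < 0 || ss >= S)
                continue;
              if (at(ii, jj, ss) > v) ok = false;
            }
        if (ok) {
          rows.push_back(i);
          cols.push_back(j);
          scales.push_back(s + 1);
          vals.push_back(v);
        }
      }
  NumericMatrix out(rows.size(), 4);
  for (size_t t = 0; t < rows.size(); ++t) {
    out(t, 0) = rows[t];
    out(t, 1) = cols[t];
    out(t, 2) = scales[t];
    out(t, 3) = vals[t];
  }
  return out;
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n, -1) {}
  int find(int x) {
    while (parent[x] >= 0) {
      if (parent[parent[x]] >= 0) parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void link(int child, int root) { parent[child] = root; }
};

// Topographic prominence of every local peak, by descending-order
// union-find: when two catchments merge at height h, the component with the
// lower peak receives prominence (peak - h). The globally highest peak gets
// (peak - image minimum). Returns columns: row, col, height, prominence.
// [[Rcpp::export]]
NumericMatrix cpp_peak_prominence(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  const long N = (long)H * W;
  std::vector<long> idx(N);
  for (long t = 0; t < N; ++t) idx[t] = t;
  const double* p = img.begin();  // column-major
  std::stable_sort(idx.begin(), idx.end(),
                   [&](long a, long b) { return p[a] > p[b]; });
  DSU dsu((int)N);
  std::vector<char> seen(N, 0);
  // per-root peak info: peak pixel index and height
  std::vector<long> comp_peak(N, -1);
  std::vector<double> peak_h(N, 0), prom(N, -1);
  std::vector<long> peaks;
  double minv = *std::min_element(p, p + N);
  for (long t = 0; t < N; ++t) {
    long q = idx[t];
    int i = (int)(q % H), j = (int)(q / H);
    double v = p[q];
    // collect distinct processed neighbour roots
    long roots[8];
    int nr = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        long nb = (long)ii + (long)H * jj;
        if (!seen[nb]) continue;
        long r = dsu.find((int)nb);
        bool dup = false;
        for (int a = 0; a < nr; ++a)
          if (roots[a] == r) dup = true;
        if (!dup) roots[nr++] = r;
      }
    seen[q] = 1;
    if (nr == 0) {  // new peak
      comp_peak[q] = q;
      peak_h[q] = v;
      peaks.push_back(q);
      continue;
    }
    // attach to highest-peak root; others die here with prominence
    int best = 0;
    for (int a = 1; a < nr; ++a)
      if (peak_h[roots[a]] > peak_h[roots[best]]) best = a;
    long broot = roots[best];
    dsu.link((int)q, (int)broot);
    for (int a = 0; a < nr; ++a) {
      if (a == best) continue;
      long r = roots[a];
      prom[comp_peak[r]] = peak_h[r] - v;
      dsu.link((int)r, (int)broot);
    }
  }
  NumericMatrix out(peaks.size(), 4);
  for (size_t t = 0; t < peaks.size(); ++t) {
    long q = peaks[t];
    out(t, 0) = q % H;
    out(t, 1) = q / H;
    out(t, 2) = p[q];
    out(t, 3) = prom[q] >= 0 ? prom[q] : p[q] - minv;
  }
  return out;
}
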