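// 3D voxel-grid primitives: connected-component labeling, exact anisotropic
// Euclidean distance transform, small median filter, marker-based watershed.
// All arrays arrive in R's column-major layout with dim = (n1, n2, n3) and a
// physical spacing per dimension; the code is agnostic to axis meaning.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline long idx3(int i, int j, int k, int n1, int n2) {
  return (long)i + (long)n1 * ((long)j + (long)n2 * (long)k);
}

// neighbor offsets for 6/18/26 connectivity
static std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int nz = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({di, dj, dk});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const long n = (long)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  auto off = neighbor_offsets(connectivity);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int i = (int)(p % n1);
      int j = (int)((p / n1) % n2);
      int k = (int)(p / ((long)n1 * n2));
      for (auto &o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
        long q = idx3(ii, jj, kk, n1, n2);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) on a line of
// values f at sample positions x_i = i * s; writes result back into f.
static void dt1d(std::vector<double> &f, double s, std::vector<int> &v,
                 std::vector<double> &z, std::vector<double> &d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { continue; }
    double sq = (double)q * s, sv;
    double num, den, inter = 0;
    while (true) {
      sv = (double)v[k] * s;
      num = (f[q] + sq * sq) - (f[v[k]] + sv * sv);
      den = 2.0 * sq - 2.0 * sv;
      inter = num / den;
      if (k > 0 && inter <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = (double)q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - (double)v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (physical units) to the nearest feature voxel.
// Voxels where feature is TRUE get 0.  No feature at all -> Inf everywhere.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const long n = (long)n1 * n2 * n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (long p = 0; p < n; ++p) out[p] = feature[p] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), z(nmax + 1), d(nmax);
  std::vector<int> v(nmax);

  // pass along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      bool any = false;
      for (int i = 0; i < n1; ++i) { f[i] = out[idx3(i,j,k,n1,n2)]; if (f[i] < INF) any = true; }
      if (!any) continue;
      f.resize(n1); dt1d(f, spacing[0], v, z, d); f.resize(nmax);
      for (int i = 0; i < n1; ++i) out[idx3(i,j,k,n1,n2)] = f[i];
    }
  // pass along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int j = 0; j < n2; ++j) { f[j] = out[idx3(i,j,k,n1,n2)]; if (f[j] < INF) any = true; }
      if (!any) continue;
      f.resize(n2); dt1d(f, spacing[1], v, z, d); f.resize(nmax);
      for (int j = 0; j < n2; ++j) out[idx3(i,j,k,n1,n2)] = f[j];
    }
  // pass along dim 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int k = 0; k < n3; ++k) { f[k] = out[idx3(i,j,k,n1,n2)]; if (f[k] < INF) any = true; }
      if (!any) continue;
      f.resize(n3); dt1d(f, spacing[2], v, z, d); f.resize(nmax);
      for (int k = 0; k < n3; ++k) out[idx3(i,j,k,n1,n2)] = f[k];
    }
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 median filter with replicated borders.
// [[Rcpp::export]]
NumericVector median3_cpp(NumericVector vol, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((long)n1 * n2 * n3);
  std::vector<double> w(27);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = std::min(std::max(i + di, 0), n1 - 1);
              int jj = std::min(std::max(j + dj, 0), n2 - 1);
              int kk = std::min(std::max(k + dk, 0), n3 - 1);
              w[m++] = vol[idx3(ii, jj, kk, n1, n2)];
            }
        std::nth_element(w.begin(), w.begin() + 13, w.end());
        out[idx3(i, j, k, n1, n2)] = w[13];
      }
  out.attr("dim") = dim;
  return out;
}

// Local maxima of a scalar field restricted to value > 0, neighborhood given
// by `radius` in voxels (Chebyshev).  Plateau voxels all qualify; the caller
// merges them with connected-component labeling.
// [[Rcpp::export]]
LogicalVector local_maxima_cpp(NumericVector vol, IntegerVector dim, int radius) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  LogicalVector out((long)n1 * n2 * n3, false);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        long p = idx3(i, j, k, n1, n2);
        double v0 = vol[p];
        if (v0 <= 0) continue;
        bool ismax = true;
        for (int dk = -radius; dk <= radius && ismax; ++dk)
          for (int dj = -radius; dj <= radius && ismax; ++dj)
            for (int di = -radius; di <= radius && ismax; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
              if (vol[idx3(ii, jj, kk, n1, n2)] > v0) ismax = false;
            }
        if (ismax) out[p] = true;
      }
  out.attr("dim") = dim;
  return out;
}

// Priority-flood watershed: grow labeled markers over `mask` in order of
// decreasing priority (e.g. the distance transform).  Deterministic: ties are
// broken by linear voxel index.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector priority, IntegerVector markers,
                                  LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const long n = (long)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  auto off = neighbor_offsets(26);
  typedef std::pair<double, long> Node; // (priority, -index): higher first
  std::priority_queue<Node> pq;
  for (long p = 0; p < n; ++p)
    if (markers[p] > 0 && mask[p]) { lab[p] = markers[p]; pq.push(Node(priority[p], -p)); }
  while (!pq.empty()) {
    long p = -pq.top().second; pq.pop();
    int i = (int)(p % n1);
    int j = (int)((p / n1) % n2);
    int k = (int)(p / ((long)n1 * n2));
    int lp = lab[p];
    for (auto &o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
      long q = idx3(ii, jj, kk, n1, n2);
      if (mask[q] && lab[q] == 0) { lab[q] = lp; pq.push(Node(priority[q], -q)); }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
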