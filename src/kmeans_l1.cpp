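#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hot loops for city-block (L1) k-means with componentwise-median centroid
// updates. Data are stored with frames as COLUMNS (p features x n frames) so
// each frame is contiguous in memory.

// L1 distance with early abandonment, accumulated in 4 lanes for ILP.
static inline double l1_dist(const double *x, const double *c, int p,
                             double best) {
  double d = 0.0;
  int i0 = 0;
  while (i0 < p) {
    const int end = std::min(p, i0 + 256);
    double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
    int i = i0;
    for (; i + 4 <= end; i += 4) {
      s0 += std::abs(x[i] - c[i]);
      s1 += std::abs(x[i + 1] - c[i + 1]);
      s2 += std::abs(x[i + 2] - c[i + 2]);
      s3 += std::abs(x[i + 3] - c[i + 3]);
    }
    for (; i < end; ++i) s0 += std::abs(x[i] - c[i]);
    d += s0 + s1 + s2 + s3;
    if (d >= best) return d;
    i0 = end;
  }
  return d;
}

// Nearest centroid by L1 distance for every frame.
// X: p x n (frames in columns), C: p x k (centroids in columns).
// Returns 1-based assignment and the L1 distance to the assigned centroid.
// [[Rcpp::export(name = ".l1_nearest")]]
List l1_nearest(NumericMatrix X, NumericMatrix C) {
  const int p = X.nrow(), n = X.ncol(), k = C.ncol();
  if (C.nrow() != p) stop("centroid dimension mismatch");
  IntegerVector assign(n);
  NumericVector dist(n);
  const double *xp = REAL(X), *cp = REAL(C);
  for (int j = 0; j < n; ++j) {
    const double *x = xp + (size_t)j * p;
    double best = R_PosInf;
    int besti = 0;
    for (int c = 0; c < k; ++c) {
      double d = l1_dist(x, cp + (size_t)c * p, p, best);
      if (d < best) { best = d; besti = c; }
    }
    assign[j] = besti + 1;
    dist[j] = best;
  }
  return List::create(_["assignment"] = assign, _["distance"] = dist);
}

static double median_inplace(double *v, int m) {
  const int h = m / 2;
  std::nth_element(v, v + h, v + m);
  double med = v[h];
  if (m % 2 == 0) med = 0.5 * (med + *std::max_element(v, v + h));
  return med;
}

// Componentwise median of the frames assigned to each cluster.
// Features are processed in blocks: one sequential pass over the frame-major
// matrix scatters each block into per-cluster flat buffers, then medians are
// taken segment-wise. Empty clusters yield NA columns (caller reseeds).
// [[Rcpp::export(name = ".group_col_medians")]]
NumericMatrix group_col_medians(NumericMatrix X, IntegerVector assign, int k) {
  const int p = X.nrow(), n = X.ncol();
  if (assign.size() != n) stop("assignment length mismatch");
  NumericMatrix M(p, k);
  std::vector<int> sizes(k, 0);
  for (int j = 0; j < n; ++j) {
    const int a = assign[j] - 1;
    if (a < 0 || a >= k) stop("assignment out of range");
    ++sizes[a];
  }
  const int BLOCK = 64;
  const double *xp = REAL(X);
  std::vector<double> flat((size_t)n * BLOCK);
  std::vector<size_t> base(k);  // buffer start of each cluster's block rows
  std::vector<int> fill(k);
  for (int i0 = 0; i0 < p; i0 += BLOCK) {
    const int bw = std::min(BLOCK, p - i0);
    size_t off = 0;
    for (int c = 0; c < k; ++c) {
      base[c] = off;
      off += (size_t)sizes[c] * bw;
      fill[c] = 0;
    }
    for (int j = 0; j < n; ++j) {
      const int a = assign[j] - 1;
      const double *x = xp + (size_t)j * p + i0;
      double *dst = &flat[base[a] + fill[a]];
      const int m = sizes[a];
      for (int b = 0; b < bw; ++b) dst[(size_t)b * m] = x[b];
      ++fill[a];
    }
    for (int c = 0; c < k; ++c) {
      const int m = sizes[c];
      for (int b = 0; b < bw; ++b) {
        M(i0 + b, c) = m ? median_inplace(&flat[base[c] + (size_t)b * m], m)
                         : NA_REAL;
      }
    }
  }
  return M;
}
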