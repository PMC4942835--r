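// Contact-based observables over snapshot ensembles. Positions come in as an
// N x 3 x T array (unwrapped coordinates); `edge` > 0 switches on the
// minimum-image convention for distances.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

namespace {
inline double min_image(double d, double L) {
  return L > 0 ? d - L * std::nearbyint(d / L) : d;
}

inline double dist2(const double* arr, int N, R_xlen_t off, int i, int j,
                    double L) {
  double dx = min_image(arr[off + i] - arr[off + j], L);
  double dy = min_image(arr[off + N + i] - arr[off + N + j], L);
  double dz = min_image(arr[off + 2 * (R_xlen_t)N + i] - arr[off + 2 * (R_xlen_t)N + j], L);
  return dx * dx + dy * dy + dz * dz;
}
}

// [[Rcpp::export]]
NumericMatrix cpp_contact_map(NumericVector arr, double threshold, double edge) {
  IntegerVector dim = arr.attr("dim");
  int N = dim[0], T = dim[2];
  double thr2 = threshold * threshold;
  const double* p = arr.begin();
  NumericMatrix out(N, N);
  for (int t = 0; t < T; ++t) {
    R_xlen_t off = (R_xlen_t)t * 3 * N;
    for (int i = 0; i < N; ++i) {
      out(i, i) += 1.0;
      for (int j = i + 1; j < N; ++j)
        if (dist2(p, N, off, i, j, edge) <= thr2) {
          out(i, j) += 1.0; out(j, i) += 1.0;
        }
    }
    if (t % 20 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) out(i, j) /= T;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_r2_vs_s(NumericVector arr) {
  IntegerVector dim = arr.attr("dim");
  int N = dim[0], T = dim[2];
  const double* p = arr.begin();
  NumericVector out(N - 1);
  for (int t = 0; t < T; ++t) {
    R_xlen_t off = (R_xlen_t)t * 3 * N;
    for (int s = 1; s < N; ++s) {
      double acc = 0;
      for (int i = 0; i + s < N; ++i) acc += dist2(p, N, off, i, i + s, -1.0);
      out[s - 1] += acc / (N - s);
    }
  }
  for (int s = 0; s < N - 1; ++s) out[s] /= T;
  return out;
}

// P(three beads i, i+s1, i+s1+s2 pairwise in contact), averaged over i and t.
// [[Rcpp::export]]
NumericMatrix cpp_triplet_grid(NumericVector arr, double threshold, int smax,
                               double edge) {
  IntegerVector dim = arr.attr("dim");
  int N = dim[0], T = dim[2];
  if (smax > N - 2) smax = N - 2;
  double thr2 = threshold * threshold;
  const double* p = arr.begin();
  NumericMatrix out(smax, smax);
  for (int t = 0; t < T; ++t) {
    R_xlen_t off = (R_xlen_t)t * 3 * N;
    for (int s1 = 1; s1 <= smax; ++s1)
      for (int s2 = 1; s2 <= smax; ++s2) {
        if (s1 + s2 >= N) continue;
        int hits = 0, tot = N - s1 - s2;
        for (int i = 0; i < tot; ++i) {
          int j = i + s1, k = i + s1 + s2;
          if (dist2(p, N, off, i, j, edge) <= thr2 &&
              dist2(p, N, off, j, k, edge) <= thr2 &&
              dist2(p, N, off, i, k, edge) <= thr2) ++hits;
        }
        out(s1 - 1, s2 - 1) += (double)hits / tot;
      }
    Rcpp::checkUserInterrupt();
  }
  for (int a = 0; a < smax; ++a)
    for (int b = 0; b < smax; ++b) out(a, b) /= T;
  return out;
}

// Mean number (per snapshot) of connected components of the contact graph
// over the given probe sites (0-based bead indices), with exactly n members,
// n = 1..length(sites). Probe sites make the statistic non-degenerate: the
// full-bead graph is always connected through backbone neighbours once the
// threshold exceeds the bond length.
// [[Rcpp::export]]
NumericVector cpp_manybody_components(NumericVector arr, double threshold,
                                      double edge, IntegerVector sites) {
  IntegerVector dim = arr.attr("dim");
  int N = dim[0], T = dim[2];
  int ns = sites.size();
  double thr2 = threshold * threshold;
  const double* p = arr.begin();
  NumericVector out(ns);
  std::vector<int> parent(ns), sz(ns);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int t = 0; t < T; ++t) {
    R_xlen_t off = (R_xlen_t)t * 3 * N;
    for (int i = 0; i < ns; ++i) { parent[i] = i; sz[i] = 1; }
    for (int i = 0; i < ns; ++i)
      for (int j = i + 1; j < ns; ++j)
        if (dist2(p, N, off, sites[i], sites[j], edge) <= thr2) {
          int a = find(i), b = find(j);
          if (a != b) {
            if (sz[a] < sz[b]) std::swap(a, b);
            parent[b] = a; sz[a] += sz[b];
          }
        }
    for (int i = 0; i < ns; ++i)
      if (find(i) == i) out[sz[i] - 1] += 1.0;
    if (t % 20 == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < ns; ++k) out[k] /= T;
  return out;
}
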