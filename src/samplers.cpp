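// Reference-ensemble samplers: cubic-lattice pivot Monte Carlo for the
// self-avoiding walk (coil/SAW universality class) and ideal Gaussian chains
// (theta-point reference). Both can stream contact/distance statistics so
// large ensembles never have to be materialised in R.
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <random>
#include <cstdint>
using namespace Rcpp;

namespace {

struct P3 { int x, y, z; };

inline std::int64_t key_of(const P3& p) {
  const std::int64_t B = 1 << 21, H = 1 << 20;
  return ((std::int64_t)(p.x + H) * B + (p.y + H)) * B + (p.z + H);
}

// the 48 octahedral symmetries as (permutation, signs)
struct Sym { int perm[3]; int sign[3]; };

std::vector<Sym> all_syms() {
  std::vector<Sym> out;
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int p = 0; p < 6; ++p)
    for (int s = 0; s < 8; ++s) {
      Sym sym;
      for (int d = 0; d < 3; ++d) {
        sym.perm[d] = perms[p][d];
        sym.sign[d] = (s >> d) & 1 ? -1 : 1;
      }
      out.push_back(sym);
    }
  return out;
}

inline P3 apply_sym(const Sym& s, const P3& v) {
  int c[3] = {v.x, v.y, v.z};
  P3 out;
  out.x = s.sign[0] * c[s.perm[0]];
  out.y = s.sign[1] * c[s.perm[1]];
  out.z = s.sign[2] * c[s.perm[2]];
  return out;
}

class Pivot {
public:
  int n;
  std::vector<P3> w;
  std::unordered_set<std::int64_t> occ;
  std::vector<Sym> syms;
  std::mt19937_64 rng;

  Pivot(int n_, std::uint64_t seed) : n(n_), syms(all_syms()) {
    rng.seed(seed ? seed : 1u);
    w.resize(n);
    for (int i = 0; i < n; ++i) w[i] = {i, 0, 0}; // rod start
    occ.reserve(2 * n);
    for (int i = 0; i < n; ++i) occ.insert(key_of(w[i]));
  }

  bool move() {
    int p = (int)(rng() % (std::uint64_t)n);
    int si = 1 + (int)(rng() % 47ULL); // skip identity (index 0)
    const Sym& s = syms[si];
    P3 piv = w[p];
    // transform the tail p+1..n-1 about the pivot
    std::vector<P3> newtail;
    newtail.reserve(n - p - 1);
    // remove tail from occupancy
    for (int i = p + 1; i < n; ++i) occ.erase(key_of(w[i]));
    bool ok = true;
    for (int i = p + 1; i < n; ++i) {
      P3 d = {w[i].x - piv.x, w[i].y - piv.y, w[i].z - piv.z};
      P3 t = apply_sym(s, d);
      P3 np = {piv.x + t.x, piv.y + t.y, piv.z + t.z};
      if (!occ.insert(key_of(np)).second) { ok = false; break; }
      newtail.push_back(np);
    }
    if (ok) {
      for (int i = p + 1; i < n; ++i) w[i] = newtail[i - p - 1];
      return true;
    }
    // rollback
    for (const P3& q : newtail) occ.erase(key_of(q));
    for (int i = p + 1; i < n; ++i) occ.insert(key_of(w[i]));
    return false;
  }
};

} // namespace

// Stream statistics over a pivot-sampled SAW ensemble.
// Returns contact counts per separation s (Euclidean threshold), pair totals,
// sum of squared distances per s, per-sample Rg and end-to-end distance.
// [[Rcpp::export]]
List cpp_saw_pivot_stats(int n, int n_samples, int stride, int burnin,
                         double threshold, int smax, double seed) {
  Pivot pv(n, (std::uint64_t)seed);
  for (int i = 0; i < burnin; ++i) pv.move();
  double thr2 = threshold * threshold;
  if (smax > n - 1) smax = n - 1;
  std::vector<double> contacts(smax + 1, 0.0), r2sum(smax + 1, 0.0);
  NumericVector rg(n_samples), e2e(n_samples);
  for (int samp = 0; samp < n_samples; ++samp) {
    for (int m = 0; m < stride; ++m) pv.move();
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) { cx += pv.w[i].x; cy += pv.w[i].y; cz += pv.w[i].z; }
    cx /= n; cy /= n; cz /= n;
    double sq = 0;
    for (int i = 0; i < n; ++i) {
      double dx = pv.w[i].x - cx, dy = pv.w[i].y - cy, dz = pv.w[i].z - cz;
      sq += dx * dx + dy * dy + dz * dz;
    }
    rg[samp] = std::sqrt(sq / n);
    {
      double dx = pv.w[n - 1].x - pv.w[0].x, dy = pv.w[n - 1].y - pv.w[0].y,
             dz = pv.w[n - 1].z - pv.w[0].z;
      e2e[samp] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    for (int s = 1; s <= smax; ++s) {
      const P3* W = pv.w.data();
      for (int i = 0; i + s < n; ++i) {
        double dx = W[i].x - W[i + s].x, dy = W[i].y - W[i + s].y,
               dz = W[i].z - W[i + s].z;
        double d2 = dx * dx + dy * dy + dz * dz;
        r2sum[s] += d2;
        if (d2 <= thr2) contacts[s] += 1.0;
      }
    }
    if (samp % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector cont(smax), pairs(smax), r2(smax);
  for (int s = 1; s <= smax; ++s) {
    cont[s - 1] = contacts[s];
    pairs[s - 1] = (double)(n - s) * n_samples;
    r2[s - 1] = r2sum[s] / ((double)(n - s) * n_samples);
  }
  return List::create(_["s"] = seq_len(smax), _["contacts"] = cont,
                      _["pairs"] = pairs, _["r2"] = r2,
                      _["rg"] = rg, _["e2e"] = e2e);
}

// Materialise a (small) pivot-SAW ensemble as an n x 3 x n_samples array.
// [[Rcpp::export]]
NumericVector cpp_saw_pivot_sample(int n, int n_samples, int stride,
                                   int burnin, double seed) {
  Pivot pv(n, (std::uint64_t)seed);
  for (int i = 0; i < burnin; ++i) pv.move();
  NumericVector out((R_xlen_t)n * 3 * n_samples);
  for (int samp = 0; samp < n_samples; ++samp) {
    for (int m = 0; m < stride; ++m) pv.move();
    for (int i = 0; i < n; ++i) {
      out[(R_xlen_t)samp * 3 * n + 0 * n + i] = pv.w[i].x;
      out[(R_xlen_t)samp * 3 * n + 1 * n + i] = pv.w[i].y;
      out[(R_xlen_t)samp * 3 * n + 2 * n + i] = pv.w[i].z;
    }
    if (samp % 50 == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(n, 3, n_samples);
  return out;
}

// Stream the same statistics over ideal Gaussian chains with bond length b.
// [[Rcpp::export]]
List cpp_gaussian_chain_stats(int n, double b, int n_samples,
                              double threshold, int smax, double seed) {
  std::mt19937_64 rng((std::uint64_t)seed ? (std::uint64_t)seed : 1u);
  std::normal_distribution<double> g(0.0, b / std::sqrt(3.0));
  double thr2 = threshold * threshold;
  if (smax > n - 1) smax = n - 1;
  std::vector<double> contacts(smax + 1, 0.0), r2sum(smax + 1, 0.0);
  NumericVector rg(n_samples);
  std::vector<double> X(n), Y(n), Z(n);
  for (int samp = 0; samp < n_samples; ++samp) {
    X[0] = Y[0] = Z[0] = 0.0;
    for (int i = 1; i < n; ++i) {
      X[i] = X[i - 1] + g(rng);
      Y[i] = Y[i - 1] + g(rng);
      Z[i] = Z[i - 1] + g(rng);
    }
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) { cx += X[i]; cy += Y[i]; cz += Z[i]; }
    cx /= n; cy /= n; cz /= n;
    double sq = 0;
    for (int i = 0; i < n; ++i) {
      double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
      sq += dx * dx + dy * dy + dz * dz;
    }
    rg[samp] = std::sqrt(sq / n);
    for (int s = 1; s <= smax; ++s)
      for (int i = 0; i + s < n; ++i) {
        double dx = X[i] - X[i + s], dy = Y[i] - Y[i + s], dz = Z[i] - Z[i + s];
        double d2 = dx * dx + dy * dy + dz * dz;
        r2sum[s] += d2;
        if (d2 <= thr2) contacts[s] += 1.0;
      }
    if (samp % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector cont(smax), pairs(smax), r2(smax);
  for (int s = 1; s <= smax; ++s) {
    cont[s - 1] = contacts[s];
    pairs[s - 1] = (double)(n - s) * n_samples;
    r2[s - 1] = r2sum[s] / ((double)(n - s) * n_samples);
  }
  return List::create(_["s"] = seq_len(smax), _["contacts"] = cont,
                      _["pairs"] = pairs, _["r2"] = r2, _["rg"] = rg);
}
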