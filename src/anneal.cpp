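// Metropolis simulated annealing of a per-bead colour/multiplicity profile
// against a target contact matrix, scored through the fast surrogate map
//   raw_ij = P0(|i-j|) * (1 + kappa * sum_c min(m_ic, m_jc))
// with cost = mean((rownorm(target) - rownorm(raw))^2) + lambda * sum(m).
// Moves: single-bead multiplicity +-1 in one colour, or a two-bead profile swap.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
using namespace Rcpp;

namespace {

struct AnnealState {
  int N, C, m_max;
  double kappa, lambda;
  std::vector<double> P0;       // length N, P0[s] for |i-j| = s
  std::vector<double> wdiag;    // length N, per-separation weight in the cost
  std::vector<double> Tn;       // row-normalised target, N*N
  std::vector<int> mult;        // N*C
  std::vector<double> raw;      // N*N surrogate (unnormalised)
  std::vector<double> rowsum;   // N

  inline int m(int i, int c) const { return mult[(size_t)i * C + c]; }

  double overlap(int i, int j) const {
    double s = 0;
    for (int c = 0; c < C; ++c)
      s += std::min(m(i, c), m(j, c));
    return s;
  }

  void rebuild() {
    for (int i = 0; i < N; ++i) {
      double rs = 0;
      for (int j = 0; j < N; ++j) {
        double v = P0[std::abs(i - j)] * (1.0 + kappa * overlap(i, j));
        raw[(size_t)i * N + j] = v;
        rs += v;
      }
      rowsum[i] = rs;
    }
  }

  double distance_cost() const {
    double acc = 0;
    for (int i = 0; i < N; ++i) {
      double inv = 1.0 / rowsum[i];
      const double* R = &raw[(size_t)i * N];
      const double* T = &Tn[(size_t)i * N];
      for (int j = 0; j < N; ++j) {
        double d = T[j] - R[j] * inv;
        acc += wdiag[std::abs(i - j)] * d * d;
      }
    }
    return acc / ((double)N * N);
  }

  double total_mult() const {
    double s = 0;
    for (int v : mult) s += v;
    return s;
  }

  double cost() const { return distance_cost() + lambda * total_mult(); }

  // set bead i's multiplicity vector; updates raw and rowsum incrementally
  void set_bead(int i, const std::vector<int>& mv) {
    for (int c = 0; c < C; ++c) mult[(size_t)i * C + c] = mv[c];
    double rs = 0;
    for (int j = 0; j < N; ++j) {
      double v = P0[std::abs(i - j)] * (1.0 + kappa * overlap(i, j));
      double old = raw[(size_t)i * N + j];
      raw[(size_t)i * N + j] = v;
      rs += v;
      if (j != i) {
        rowsum[j] += v - raw[(size_t)j * N + i];
        raw[(size_t)j * N + i] = v;
      }
    }
    rowsum[i] = rs;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_anneal_profile(NumericMatrix target, NumericVector baseline,
                        IntegerMatrix init_mult, double kappa, double lambda,
                        int m_max, double t0, double cool, int sweeps_per_level,
                        int n_levels, double seed,
                        Nullable<NumericVector> diag_weights = R_NilValue) {
  AnnealState st;
  st.N = target.nrow();
  st.C = init_mult.ncol();
  st.m_max = m_max;
  st.kappa = kappa;
  st.lambda = lambda;
  if (init_mult.nrow() != st.N) stop("init_mult rows must match target size");
  if ((int)baseline.size() < st.N) stop("baseline must cover separations 0..N-1");
  st.P0.assign(baseline.begin(), baseline.begin() + st.N);
  for (int s = 0; s < st.N; ++s)
    if (!(st.P0[s] > 0)) stop("baseline must be strictly positive");
  if (diag_weights.isNotNull()) {
    NumericVector w(diag_weights);
    if ((int)w.size() < st.N) stop("diag_weights must cover separations 0..N-1");
    st.wdiag.assign(w.begin(), w.begin() + st.N);
  } else {
    st.wdiag.assign(st.N, 1.0);
  }
  st.Tn.resize((size_t)st.N * st.N);
  for (int i = 0; i < st.N; ++i) {
    double rs = 0;
    for (int j = 0; j < st.N; ++j) rs += target(i, j);
    if (rs <= 0) stop("target has an all-zero row");
    for (int j = 0; j < st.N; ++j) st.Tn[(size_t)i * st.N + j] = target(i, j) / rs;
  }
  st.mult.resize((size_t)st.N * st.C);
  for (int i = 0; i < st.N; ++i)
    for (int c = 0; c < st.C; ++c) st.mult[(size_t)i * st.C + c] = init_mult(i, c);
  st.raw.resize((size_t)st.N * st.N);
  st.rowsum.resize(st.N);
  st.rebuild();

  std::mt19937_64 rng((std::uint64_t)seed ? (std::uint64_t)seed : 1u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto rint = [&](int k) { return (int)(rng() % (std::uint64_t)k); };

  double cur = st.cost();
  std::vector<int> best_mult = st.mult;
  double best = cur;

  // auto temperature: median uphill jump of probe moves
  double T0 = t0;
  if (T0 <= 0) {
    std::vector<double> jumps;
    for (int p = 0; p < 200; ++p) {
      int i = rint(st.N), c = rint(st.C);
      std::vector<int> mv(st.C), old(st.C);
      for (int cc = 0; cc < st.C; ++cc) old[cc] = mv[cc] = st.m(i, cc);
      mv[c] += (rng() & 1) ? 1 : -1;
      if (mv[c] < 0 || mv[c] > st.m_max) continue;
      st.set_bead(i, mv);
      double nc = st.cost();
      if (nc > cur) jumps.push_back(nc - cur);
      st.set_bead(i, old);
    }
    if (jumps.empty()) T0 = 1e-4;
    else {
      std::nth_element(jumps.begin(), jumps.begin() + jumps.size() / 2, jumps.end());
      T0 = jumps[jumps.size() / 2] / std::log(2.0);
    }
    if (!(T0 > 0)) T0 = 1e-8;
  }

  NumericVector trace_T(n_levels), trace_best(n_levels), trace_acc(n_levels);
  double T = T0;
  int zero_acc_levels = 0;
  bool converged_flag = true;
  for (int lev = 0; lev < n_levels; ++lev) {
    int n_moves = sweeps_per_level * st.N, n_acc = 0;
    for (int mv_i = 0; mv_i < n_moves; ++mv_i) {
      double u_kind = unif(rng);
      if (u_kind < 0.7 || st.N < 2) {
        int i = rint(st.N), c = rint(st.C);
        std::vector<int> mv(st.C), old(st.C);
        for (int cc = 0; cc < st.C; ++cc) old[cc] = mv[cc] = st.m(i, cc);
        mv[c] += (rng() & 1) ? 1 : -1;
        if (mv[c] < 0 || mv[c] > st.m_max) continue;
        st.set_bead(i, mv);
        double nc = st.cost();
        if (nc <= cur || unif(rng) < std::exp(-(nc - cur) / T)) {
          cur = nc; ++n_acc;
          if (cur < best) { best = cur; best_mult = st.mult; }
        } else {
          st.set_bead(i, old);
        }
      } else {
        int i = rint(st.N), j = rint(st.N);
        if (i == j) continue;
        std::vector<int> mi(st.C), mj(st.C);
        for (int cc = 0; cc < st.C; ++cc) { mi[cc] = st.m(i, cc); mj[cc] = st.m(j, cc); }
        if (mi == mj) continue;
        st.set_bead(i, mj); st.set_bead(j, mi);
        double nc = st.cost();
        if (nc <= cur || unif(rng) < std::exp(-(nc - cur) / T)) {
          cur = nc; ++n_acc;
          if (cur < best) { best = cur; best_mult = st.mult; }
        } else {
          st.set_bead(i, mi); st.set_bead(j, mj);
        }
      }
    }
    trace_T[lev] = T;
    trace_best[lev] = best;
    trace_acc[lev] = (double)n_acc / n_moves;
    zero_acc_levels = (n_acc == 0) ? zero_acc_levels + 1 : 0;
    if (zero_acc_levels >= 3 && lev >= n_levels - 3) converged_flag = false;
    T *= cool;
    Rcpp::checkUserInterrupt();
  }
  // non-convergence: no accepted move in the final 3 levels
  bool no_final_accept = true;
  for (int lev = std::max(0, n_levels - 3); lev < n_levels; ++lev)
    if (trace_acc[lev] > 0) no_final_accept = false;

  IntegerMatrix mout(st.N, st.C);
  for (int i = 0; i < st.N; ++i)
    for (int c = 0; c < st.C; ++c) mout(i, c) = best_mult[(size_t)i * st.C + c];
  return List::create(_["multiplicities"] = mout, _["best_cost"] = best,
                      _["t0"] = T0,
                      _["trace"] = DataFrame::create(_["temperature"] = trace_T,
                                                     _["best_cost"] = trace_best,
                                                     _["acceptance"] = trace_acc),
                      _["stalled_final_levels"] = no_final_accept);
}

// Surrogate map evaluation (shared kernel with the annealer via the same
// formula; exported for the R-level surrogate_contact_matrix).
// [[Rcpp::export]]
NumericMatrix cpp_surrogate(NumericVector baseline, IntegerMatrix mult,
                            double kappa) {
  int N = mult.nrow(), C = mult.ncol();
  NumericMatrix out(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = i; j < N; ++j) {
      double ov = 0;
      for (int c = 0; c < C; ++c)
        ov += std::min(mult(i, c), mult(j, c));
      double v = baseline[std::abs(i - j)] * (1.0 + kappa * ov);
      out(i, j) = v; out(j, i) = v;
    }
  return out;
}
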