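// Langevin (BAOAB) dynamics of the strings-and-binders system:
// a FENE bead-spring chain plus diffusing binders in a periodic cubic box.
// Bead-bead and binder-binder pairs are purely repulsive (WCA); bead-binder
// pairs with a matching colour interact through a truncated-and-shifted
// Lennard-Jones well of depth E_int * multiplicity.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
using namespace Rcpp;

namespace {

const double WCA_CUT = std::pow(2.0, 1.0 / 6.0);

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct Params {
  double eps_rep, rcut_attr, fene_k, fene_r0, kT, edge, gamma, skin;
};

class Engine {
public:
  int n_beads, n_binders, n_colors, P;
  Params pp;
  std::vector<double> x, v, f;        // 3*P, unwrapped positions
  std::vector<double> eps_att;        // n_beads * n_colors well depths
  std::vector<int> binder_col;        // 0-based, length n_binders
  double shift_unit;                  // LJ energy shift per unit depth
  double rv2;                         // neighbour-list cutoff^2 (incl. skin)
  double rc2_attr, rc2_wca;
  bool overstretched;                 // set by forces() when a bond >= r0
  std::vector<int> pair_i, pair_j;    // Verlet half list
  std::vector<double> x_build;        // positions at last list build
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  Engine(const NumericMatrix& pos, const IntegerMatrix& beadmult,
         const IntegerVector& bcol, const NumericVector& eint,
         const Params& p, std::uint64_t seed)
    : pp(p), gauss(0.0, 1.0) {
    n_beads = beadmult.nrow();
    n_colors = beadmult.ncol();
    n_binders = bcol.size();
    P = pos.nrow();
    if (P != n_beads + n_binders) stop("positions rows must equal beads + binders");
    x.resize(3 * P); v.assign(3 * P, 0.0); f.assign(3 * P, 0.0);
    for (int i = 0; i < P; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
    eps_att.assign((size_t)n_beads * std::max(1, n_colors), 0.0);
    for (int i = 0; i < n_beads; ++i)
      for (int c = 0; c < n_colors; ++c)
        eps_att[(size_t)i * n_colors + c] = eint[c] * beadmult(i, c);
    binder_col.resize(n_binders);
    for (int j = 0; j < n_binders; ++j) binder_col[j] = bcol[j] - 1;
    double s6 = std::pow(1.0 / pp.rcut_attr, 6.0);
    shift_unit = 4.0 * (s6 * s6 - s6);
    double rv = std::max(pp.rcut_attr, WCA_CUT) + pp.skin;
    rv2 = rv * rv;
    rc2_attr = pp.rcut_attr * pp.rcut_attr;
    rc2_wca = WCA_CUT * WCA_CUT;
    overstretched = false;
    rng.seed(seed ? seed : 0x9e3779b97f4a7c15ULL);
    build_list();
  }

  // well depth for a pair; 0 means WCA-only
  inline double pair_depth(int a, int b) const {
    int bead = -1, binder = -1;
    if (a < n_beads && b >= n_beads) { bead = a; binder = b - n_beads; }
    else if (b < n_beads && a >= n_beads) { bead = b; binder = a - n_beads; }
    else return 0.0;
    int c = binder_col[binder];
    if (c < 0 || c >= n_colors) return 0.0;
    return eps_att[(size_t)bead * n_colors + c];
  }

  void build_list() {
    pair_i.clear(); pair_j.clear();
    double L = pp.edge;
    double rv = std::sqrt(rv2);
    int nc = (int)std::floor(L / rv);
    if (nc < 3) {
      for (int a = 0; a < P; ++a)
        for (int b = a + 1; b < P; ++b) { pair_i.push_back(a); pair_j.push_back(b); }
    } else {
      double cw = L / nc;
      int ncell = nc * nc * nc;
      std::vector<int> head(ncell, -1), nxt(P, -1), cell_of(P);
      for (int a = 0; a < P; ++a) {
        int ix = (int)std::floor((x[3 * a] - L * std::floor(x[3 * a] / L)) / cw) % nc;
        int iy = (int)std::floor((x[3 * a + 1] - L * std::floor(x[3 * a + 1] / L)) / cw) % nc;
        int iz = (int)std::floor((x[3 * a + 2] - L * std::floor(x[3 * a + 2] / L)) / cw) % nc;
        if (ix < 0) ix += nc; if (iy < 0) iy += nc; if (iz < 0) iz += nc;
        int ci = (ix * nc + iy) * nc + iz;
        cell_of[a] = ci; nxt[a] = head[ci]; head[ci] = a;
      }
      for (int ix = 0; ix < nc; ++ix)
        for (int iy = 0; iy < nc; ++iy)
          for (int iz = 0; iz < nc; ++iz) {
            int ci = (ix * nc + iy) * nc + iz;
            for (int dx = -1; dx <= 1; ++dx)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dz = -1; dz <= 1; ++dz) {
                  int jx = (ix + dx + nc) % nc, jy = (iy + dy + nc) % nc,
                      jz = (iz + dz + nc) % nc;
                  int cj = (jx * nc + jy) * nc + jz;
                  if (cj < ci) continue;
                  for (int a = head[ci]; a >= 0; a = nxt[a]) {
                    int bstart = (cj == ci) ? nxt[a] : head[cj];
                    for (int b = bstart; b >= 0; b = nxt[b]) {
                      double ddx = min_image(x[3 * a] - x[3 * b], L);
                      double ddy = min_image(x[3 * a + 1] - x[3 * b + 1], L);
                      double ddz = min_image(x[3 * a + 2] - x[3 * b + 2], L);
                      if (ddx * ddx + ddy * ddy + ddz * ddz < rv2) {
                        pair_i.push_back(a); pair_j.push_back(b);
                      }
                    }
                  }
                }
          }
    }
    x_build = x;
  }

  void maybe_rebuild() {
    double lim = 0.25 * pp.skin * pp.skin; // (skin/2)^2
    for (int a = 0; a < P; ++a) {
      double dx = x[3 * a] - x_build[3 * a];
      double dy = x[3 * a + 1] - x_build[3 * a + 1];
      double dz = x[3 * a + 2] - x_build[3 * a + 2];
      if (dx * dx + dy * dy + dz * dz > lim) { build_list(); return; }
    }
  }

  // fills f; returns potential energy; sets `overstretched` on FENE blow-up
  double forces() {
    std::fill(f.begin(), f.end(), 0.0);
    overstretched = false;
    double U = 0.0, L = pp.edge;
    double r02 = pp.fene_r0 * pp.fene_r0;
    const size_t np = pair_i.size();
    for (size_t k = 0; k < np; ++k) {
      int a = pair_i[k], b = pair_j[k];
      double dx = min_image(x[3 * a] - x[3 * b], L);
      double dy = min_image(x[3 * a + 1] - x[3 * b + 1], L);
      double dz = min_image(x[3 * a + 2] - x[3 * b + 2], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      double depth = pair_depth(a, b);
      if (depth > 0.0) {
        if (r2 >= rc2_attr) continue;
        double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
        U += 4.0 * depth * (ir12 - ir6) - depth * shift_unit;
        double fr = 24.0 * depth * (2.0 * ir12 - ir6) * ir2;
        f[3 * a] += fr * dx; f[3 * a + 1] += fr * dy; f[3 * a + 2] += fr * dz;
        f[3 * b] -= fr * dx; f[3 * b + 1] -= fr * dy; f[3 * b + 2] -= fr * dz;
      } else {
        if (r2 >= rc2_wca) continue;
        double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
        U += 4.0 * pp.eps_rep * (ir12 - ir6) + pp.eps_rep;
        double fr = 24.0 * pp.eps_rep * (2.0 * ir12 - ir6) * ir2;
        f[3 * a] += fr * dx; f[3 * a + 1] += fr * dy; f[3 * a + 2] += fr * dz;
        f[3 * b] -= fr * dx; f[3 * b + 1] -= fr * dy; f[3 * b + 2] -= fr * dz;
      }
    }
    // FENE bonds along the chain (in addition to WCA above)
    for (int i = 0; i + 1 < n_beads; ++i) {
      int a = i, b = i + 1;
      double dx = min_image(x[3 * a] - x[3 * b], L);
      double dy = min_image(x[3 * a + 1] - x[3 * b + 1], L);
      double dz = min_image(x[3 * a + 2] - x[3 * b + 2], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= 0.9801 * r02) { overstretched = true; continue; }
      double den = 1.0 - r2 / r02;
      U += -0.5 * pp.fene_k * r02 * std::log(den);
      double fr = -pp.fene_k / den;
      f[3 * a] += fr * dx; f[3 * a + 1] += fr * dy; f[3 * a + 2] += fr * dz;
      f[3 * b] -= fr * dx; f[3 * b + 1] -= fr * dy; f[3 * b + 2] -= fr * dz;
    }
    return U;
  }

  void draw_velocities() {
    for (int i = 0; i < 3 * P; ++i) v[i] = std::sqrt(pp.kT) * gauss(rng);
  }

  // one BAOAB step at timestep dt; returns false on overstretch/NaN
  bool baoab(double dt) {
    double c1 = std::exp(-pp.gamma * dt);
    double c2 = std::sqrt((1.0 - c1 * c1) * pp.kT);
    for (int i = 0; i < 3 * P; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * P; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < 3 * P; ++i) v[i] = c1 * v[i] + c2 * gauss(rng);
    for (int i = 0; i < 3 * P; ++i) x[i] += 0.5 * dt * v[i];
    maybe_rebuild();
    forces();
    if (overstretched) return false;
    for (int i = 0; i < 3 * P; ++i) v[i] += 0.5 * dt * f[i];
    return std::isfinite(f[0]) && std::isfinite(x[0]);
  }

  // advance by dt, halving on bond overstretch (bounded recursion)
  bool advance(double dt, int depth, int& n_halved) {
    std::vector<double> xs = x, vs = v, fs = f;
    if (baoab(dt)) return true;
    x = xs; v = vs; f = fs;
    build_list(); // list may have been rebuilt at the rejected positions
    if (depth >= 8) return false;
    ++n_halved;
    return advance(0.5 * dt, depth + 1, n_halved) &&
           advance(0.5 * dt, depth + 1, n_halved);
  }

  double rg_beads() const {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n_beads; ++i) {
      cx += x[3 * i]; cy += x[3 * i + 1]; cz += x[3 * i + 2];
    }
    cx /= n_beads; cy /= n_beads; cz /= n_beads;
    double s = 0;
    for (int i = 0; i < n_beads; ++i) {
      double dx = x[3 * i] - cx, dy = x[3 * i + 1] - cy, dz = x[3 * i + 2] - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
    return std::sqrt(s / n_beads);
  }
};

Params params_from_list(const List& ff, double edge, double gamma) {
  Params p;
  p.eps_rep = as<double>(ff["eps_rep"]);
  p.rcut_attr = as<double>(ff["r_cut_attr"]);
  p.fene_k = as<double>(ff["fene_k"]);
  p.fene_r0 = as<double>(ff["fene_r0"]);
  p.kT = as<double>(ff["kT"]);
  p.edge = edge;
  p.gamma = gamma;
  p.skin = 0.3;
  return p;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerMatrix beadmult,
                IntegerVector bindercol, NumericVector eint, double edge,
                List ff, double dt, double gamma, int n_steps,
                int sample_interval, double seed) {
  if (sample_interval < 1) stop("sample_interval must be >= 1");
  Params p = params_from_list(ff, edge, gamma);
  Engine e(pos, beadmult, bindercol, eint, p, (std::uint64_t)seed);
  if (vel.nrow() == e.P) {
    for (int i = 0; i < e.P; ++i)
      for (int d = 0; d < 3; ++d) e.v[3 * i + d] = vel(i, d);
  } else {
    e.draw_velocities();
  }
  e.forces();
  if (e.overstretched) stop("initial configuration has an overstretched bond");
  int n_snap = 1 + n_steps / sample_interval;
  NumericVector traj((R_xlen_t)e.P * 3 * n_snap);
  NumericVector times(n_snap), rg(n_snap), ke(n_snap);
  auto store = [&](int s) {
    for (int i = 0; i < e.P; ++i)
      for (int d = 0; d < 3; ++d)
        traj[(R_xlen_t)s * 3 * e.P + (R_xlen_t)d * e.P + i] = e.x[3 * i + d];
    rg[s] = e.rg_beads();
    double k = 0;
    for (int i = 0; i < 3 * e.P; ++i) k += 0.5 * e.v[i] * e.v[i];
    ke[s] = k / (3.0 * e.P);
  };
  store(0); times[0] = 0.0;
  int n_halved = 0, stored = 1;
  bool ok = true;
  for (int step = 1; step <= n_steps; ++step) {
    if (!e.advance(dt, 0, n_halved)) { ok = false; break; }
    if (step % sample_interval == 0 && stored < n_snap) {
      store(stored); times[stored] = step * dt; ++stored;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (stored < n_snap) {
    // instability: keep only the stable prefix of snapshots
    NumericVector tr2((R_xlen_t)e.P * 3 * stored);
    std::copy(traj.begin(), traj.begin() + (R_xlen_t)e.P * 3 * stored, tr2.begin());
    traj = tr2;
  }
  traj.attr("dim") = IntegerVector::create(e.P, 3, stored);
  NumericMatrix vout(e.P, 3);
  for (int i = 0; i < e.P; ++i)
    for (int d = 0; d < 3; ++d) vout(i, d) = e.v[3 * i + d];
  return List::create(_["positions"] = traj,
                      _["times"] = times[Range(0, stored - 1)],
                      _["rg"] = rg[Range(0, stored - 1)],
                      _["kinetic_per_dof"] = ke[Range(0, stored - 1)],
                      _["velocities"] = vout,
                      _["n_halved_steps"] = n_halved,
                      _["stable"] = ok);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerMatrix beadmult,
                         IntegerVector bindercol, NumericVector eint,
                         double edge, List ff) {
  Params p = params_from_list(ff, edge, 0.0);
  Engine e(pos, beadmult, bindercol, eint, p, 1);
  e.forces();
  if (e.overstretched) stop("overstretched FENE bond (r >= 0.99 r0)");
  NumericMatrix out(e.P, 3);
  for (int i = 0; i < e.P; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = e.f[3 * i + d];
  return out;
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, IntegerMatrix beadmult,
                  IntegerVector bindercol, NumericVector eint,
                  double edge, List ff) {
  Params p = params_from_list(ff, edge, 0.0);
  Engine e(pos, beadmult, bindercol, eint, p, 1);
  double U = e.forces();
  if (e.overstretched) stop("overstretched FENE bond (r >= 0.99 r0)");
  return U;
}

// Place m binders uniformly in the box, at least `min_dist` (minimum image)
// away from all previously placed particles.
// [[Rcpp::export]]
NumericMatrix cpp_place_binders(NumericMatrix existing, int m, double edge,
                                double min_dist, double seed) {
  std::mt19937_64 rng((std::uint64_t)seed ? (std::uint64_t)seed : 1u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int n0 = existing.nrow();
  std::vector<double> px, py, pz;
  px.reserve(n0 + m); py.reserve(n0 + m); pz.reserve(n0 + m);
  for (int i = 0; i < n0; ++i) {
    px.push_back(existing(i, 0)); py.push_back(existing(i, 1)); pz.push_back(existing(i, 2));
  }
  double md2 = min_dist * min_dist;
  NumericMatrix out(m, 3);
  for (int k = 0; k < m; ++k) {
    bool placed = false;
    for (int t = 0; t < 20000 && !placed; ++t) {
      double cx = edge * unif(rng), cy = edge * unif(rng), cz = edge * unif(rng);
      bool ok = true;
      for (size_t j = 0; j < px.size(); ++j) {
        double dx = min_image(cx - px[j], edge);
        double dy = min_image(cy - py[j], edge);
        double dz = min_image(cz - pz[j], edge);
        if (dx * dx + dy * dy + dz * dz < md2) { ok = false; break; }
      }
      if (ok) {
        out(k, 0) = cx; out(k, 1) = cy; out(k, 2) = cz;
        px.push_back(cx); py.push_back(cy); pz.push_back(cz);
        placed = true;
      }
    }
    if (!placed) stop("binder placement failed: box too crowded");
  }
  return out;
}

// Grow a self-avoiding initial conformation with unit bonds inside a
// periodic box: no two beads closer than `min_dist` under minimum image.
// The unwrapped chain is confined to a span < edge - 1 per dimension so the
// conformation cannot wind around the torus (a wound chain is topologically
// barred from collapsing into a globule).
// [[Rcpp::export]]
NumericMatrix cpp_grow_saw(int n, double edge, double seed, double bond,
                           double min_dist, int max_restarts) {
  std::mt19937_64 rng((std::uint64_t)seed ? (std::uint64_t)seed : 1u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double md2 = min_dist * min_dist;
  double max_span = edge - 1.0;
  for (int attempt = 0; attempt < max_restarts; ++attempt) {
    std::vector<double> px(n), py(n), pz(n);
    px[0] = edge * unif(rng); py[0] = edge * unif(rng); pz[0] = edge * unif(rng);
    int i = 1;
    int stuck = 0;
    while (i < n) {
      bool placed = false;
      for (int t = 0; t < 60; ++t) {
        // uniform direction on the sphere
        double u = 2.0 * unif(rng) - 1.0, phi = 2.0 * M_PI * unif(rng);
        double s = std::sqrt(std::max(0.0, 1.0 - u * u));
        double cx = px[i - 1] + bond * s * std::cos(phi);
        double cy = py[i - 1] + bond * s * std::sin(phi);
        double cz = pz[i - 1] + bond * u;
        bool ok = true;
        // winding guard: the unwrapped span must stay below one cell
        double lox = cx, hix = cx, loy = cy, hiy = cy, loz = cz, hiz = cz;
        for (int j = 0; j < i; ++j) {
          lox = std::min(lox, px[j]); hix = std::max(hix, px[j]);
          loy = std::min(loy, py[j]); hiy = std::max(hiy, py[j]);
          loz = std::min(loz, pz[j]); hiz = std::max(hiz, pz[j]);
        }
        if (hix - lox > max_span || hiy - loy > max_span ||
            hiz - loz > max_span)
          ok = false;
        for (int j = 0; ok && j < i - 1; ++j) {
          double dx = min_image(cx - px[j], edge);
          double dy = min_image(cy - py[j], edge);
          double dz = min_image(cz - pz[j], edge);
          if (dx * dx + dy * dy + dz * dz < md2) { ok = false; break; }
        }
        if (ok) { px[i] = cx; py[i] = cy; pz[i] = cz; ++i; placed = true; break; }
      }
      if (!placed) {
        // back up a few beads and retry
        i = std::max(1, i - 8);
        if (++stuck > 50 * n) break;
      }
    }
    if (i == n) {
      NumericMatrix out(n, 3);
      for (int k = 0; k < n; ++k) { out(k, 0) = px[k]; out(k, 1) = py[k]; out(k, 2) = pz[k]; }
      return out;
    }
  }
  stop("could not place a self-avoiding initial configuration (box too crowded?)");
}
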