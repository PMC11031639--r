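// Photon Monte Carlo transport through a voxel grid with kerma-approximation
// energy deposition and history-by-history statistics.
//
// Geometry: uniform x-y lateral grid, non-uniform z plane edges (thin films
// and shields are resolved exactly). The source is a truncated isotropic
// point at (0, 0, sid); the beam travels along -z.
//
// Physics per history: ray-trace exact per-voxel path lengths accumulating
// optical depth; invert exp(-tau) for the interaction point; branch on the
// local material's partial cross sections - photoelectric (full local
// deposit), incoherent (free-electron Klein-Nishina, continue with the
// scattered photon), coherent (Thomson angular law, no deposit). Photons
// below the cutoff or leaving the grid terminate. Two scoring modes:
//  - collision: analog energy deposits at interaction sites (with optional
//    interaction splitting of primaries, the n_split mechanism);
//  - track: expected-value (track-length kerma) scoring E * mu_en * dl along
//    every segment, with the random walk itself kept analog.
// Statistics are history-by-history: all descendants of one primary are one
// history.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- counter-based per-history RNG (splitmix64 -> xoshiro256++) -----------
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t global_seed, uint64_t stream) {
    uint64_t x = global_seed ^ (stream * 0xD1B54A32D192ED03ULL + 1ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double u() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Grid {
  int nx, ny, nz;
  double ox, oy, dx, dy;
  const double *ze;          // nz + 1 ascending z edges
  const int *lab;            // 1-based material labels, nx*ny*nz
  inline int idx(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }
};

struct Tables {
  int ne, nmat;
  double e0;                 // energy of first row (keV), 1 keV spacing
  const double *mu, *muen, *fpe, *finc;  // ne x nmat, column-major
  inline double look(const double *t, double e, int m) const {
    double f = (e - e0);
    int i = (int)f;
    if (i < 0) { i = 0; f = 0.0; }
    else if (i >= ne - 1) { i = ne - 2; f = 1.0; }
    else f -= i;
    const double *col = t + (size_t)m * ne;
    return col[i] * (1.0 - f) + col[i + 1] * f;
  }
};

struct Scorer {
  int nvox;
  std::vector<double> s1, s2, hbuf;
  std::vector<int> last;
  double edep_total = 0.0, e_emitted = 0.0;
  explicit Scorer(int n) : nvox(n), s1(n), s2(n), hbuf(n), last(n, -1) {}
  inline void add(int v, double val, int hist) {
    if (last[v] != hist) {
      double b = hbuf[v];
      s1[v] += b; s2[v] += b * b;
      hbuf[v] = val; last[v] = hist;
    } else {
      hbuf[v] += val;
    }
    edep_total += val;
  }
  void flush() {
    for (int v = 0; v < nvox; ++v) {
      double b = hbuf[v];
      s1[v] += b; s2[v] += b * b;
      hbuf[v] = 0.0; last[v] = -1;
    }
  }
};

struct Photon {
  double x, y, z, ux, uy, uz, e, w;
};

// rotate direction by scattering angle (cos_t) and azimuth phi
static inline void rotate_dir(Photon &p, double cos_t, double phi, Rng &rng) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  double a1x, a1y, a1z;
  if (std::fabs(uz) < 0.99) {  // a1 = normalize(u x z-hat)
    double n = std::sqrt(ux * ux + uy * uy);
    a1x = uy / n; a1y = -ux / n; a1z = 0.0;
  } else {                     // a1 = normalize(u x x-hat)
    double n = std::sqrt(uy * uy + uz * uz);
    a1x = 0.0; a1y = uz / n; a1z = -uy / n;
  }
  // a2 = u x a1
  double a2x = uy * a1z - uz * a1y;
  double a2y = uz * a1x - ux * a1z;
  double a2z = ux * a1y - uy * a1x;
  p.ux = cos_t * ux + sin_t * (cp * a1x + sp * a2x);
  p.uy = cos_t * uy + sin_t * (cp * a1y + sp * a2y);
  p.uz = cos_t * uz + sin_t * (cp * a1z + sp * a2z);
  double n = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= n; p.uy /= n; p.uz /= n;
}

// Klein-Nishina energy sampling (composition-rejection); returns eps = E'/E
static inline double sample_kn(double e_kev, Rng &rng, double &cos_t) {
  double k = e_kev / 510.99895;
  double e0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / e0), a2 = 0.5 * (1.0 - e0 * e0);
  double eps, g;
  do {
    if (rng.u() * (a1 + a2) < a1) eps = e0 * std::exp(a1 * rng.u());
    else eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * rng.u());
    double t = (1.0 - eps) / (k * eps);
    double sint2 = t * (2.0 - t);
    g = 1.0 - eps * sint2 / (1.0 + eps * eps);
    cos_t = 1.0 - t;
  } while (rng.u() > g);
  return eps;
}

// Thomson angular sampling: pdf ~ (1 + cos^2)
static inline double sample_thomson(Rng &rng) {
  double c;
  do { c = 2.0 * rng.u() - 1.0; } while (rng.u() > 0.5 * (1.0 + c * c));
  return c;
}

// move photon to the grid boundary; false if the ray misses the grid
static bool enter_grid(const Grid &g, Photon &p) {
  double t0 = 0.0, t1 = 1e30;
  const double lo[3] = {g.ox, g.oy, g.ze[0]};
  const double hi[3] = {g.ox + g.nx * g.dx, g.oy + g.ny * g.dy, g.ze[g.nz]};
  const double pos[3] = {p.x, p.y, p.z};
  const double dir[3] = {p.ux, p.uy, p.uz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (pos[a] <= lo[a] || pos[a] >= hi[a]) return false;
    } else {
      double ta = (lo[a] - pos[a]) / dir[a];
      double tb = (hi[a] - pos[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return false;
  double t = t0 + 1e-9;
  p.x += t * p.ux; p.y += t * p.uy; p.z += t * p.uz;
  return true;
}

static inline int find_z(const Grid &g, double z) {
  int lo = 0, hi = g.nz;        // edges[lo] <= z < edges[hi]
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (z >= g.ze[mid]) lo = mid; else hi = mid;
  }
  return lo;
}

// Trace a photon flight to optical depth tau_target (or exit). If scoring
// is non-null, deposits w*E*mu_en*dl per segment (track estimator, all in
// cm via the 0.1 mm->cm factor). Returns true if an interaction occurs
// (photon position updated), false on exit.
static bool fly(const Grid &g, const Tables &tb, Photon &p, double tau_target,
                Scorer *sc, int hist, bool score_track, double *tau_out) {
  int ix = (int)std::floor((p.x - g.ox) / g.dx);
  int iy = (int)std::floor((p.y - g.oy) / g.dy);
  if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny ||
      p.z <= g.ze[0] || p.z >= g.ze[g.nz]) {
    if (!enter_grid(g, p)) { if (tau_out) *tau_out = 0.0; return false; }
    ix = (int)std::floor((p.x - g.ox) / g.dx);
    iy = (int)std::floor((p.y - g.oy) / g.dy);
    if (ix < 0) ix = 0; if (ix >= g.nx) ix = g.nx - 1;
    if (iy < 0) iy = 0; if (iy >= g.ny) iy = g.ny - 1;
  }
  int iz = find_z(g, p.z);
  int sx = (p.ux > 0) - (p.ux < 0);
  int sy = (p.uy > 0) - (p.uy < 0);
  int sz = (p.uz > 0) - (p.uz < 0);
  double inv_ux = (sx != 0) ? 1.0 / p.ux : 1e30;
  double inv_uy = (sy != 0) ? 1.0 / p.uy : 1e30;
  double inv_uz = (sz != 0) ? 1.0 / p.uz : 1e30;
  double tau = 0.0;
  const double MM2CM = 0.1;
  while (true) {
    double bx = g.ox + (ix + (sx > 0)) * g.dx;
    double by = g.oy + (iy + (sy > 0)) * g.dy;
    double bz = g.ze[iz + (sz > 0)];
    double tx = (sx != 0) ? (bx - p.x) * inv_ux : 1e30;
    double ty = (sy != 0) ? (by - p.y) * inv_uy : 1e30;
    double tz = (sz != 0) ? (bz - p.z) * inv_uz : 1e30;
    double t = std::min(tx, std::min(ty, tz));
    if (t < 0) t = 0;
    int m = g.lab[g.idx(ix, iy, iz)] - 1;
    double mu = tb.look(tb.mu, p.e, m);            // 1/cm
    double seg_tau = mu * t * MM2CM;
    if (tau + seg_tau >= tau_target) {
      double d = (tau_target - tau) / std::max(mu * MM2CM, 1e-30);
      if (sc && score_track) {
        sc->add(g.idx(ix, iy, iz),
                p.w * p.e * tb.look(tb.muen, p.e, m) * d * MM2CM, hist);
      }
      p.x += d * p.ux; p.y += d * p.uy; p.z += d * p.uz;
      if (tau_out) *tau_out = tau_target;
      return true;
    }
    if (sc && score_track) {
      sc->add(g.idx(ix, iy, iz),
              p.w * p.e * tb.look(tb.muen, p.e, m) * t * MM2CM, hist);
    }
    tau += seg_tau;
    p.x += t * p.ux; p.y += t * p.uy; p.z += t * p.uz;
    if (t == tx)      { ix += sx; if (ix < 0 || ix >= g.nx) break; }
    else if (t == ty) { iy += sy; if (iy < 0 || iy >= g.ny) break; }
    else              { iz += sz; if (iz < 0 || iz >= g.nz) break; }
  }
  if (tau_out) *tau_out = tau;
  return false;
}

struct Config {
  double pcut;
  bool primaries_only, track;
  int n_split;
};

// transport one photon (and its descendants) analogically
static void walk(const Grid &g, const Tables &tb, Photon p, Rng &rng,
                 Scorer &sc, int hist, const Config &cf) {
  bool is_primary = true;
  while (true) {
    double tau_t = -std::log(rng.u());
    if (!fly(g, tb, p, tau_t, &sc, hist, cf.track, nullptr)) return;
    int ix = (int)std::floor((p.x - g.ox) / g.dx);
    int iy = (int)std::floor((p.y - g.oy) / g.dy);
    int iz = find_z(g, p.z);
    if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny) return;
    int v = g.idx(ix, iy, iz);
    int m = g.lab[v] - 1;
    if (cf.primaries_only && is_primary) {
      if (!cf.track) sc.add(v, p.w * p.e, hist);
      return;
    }
    double u = rng.u();
    double fpe = tb.look(tb.fpe, p.e, m);
    double finc = tb.look(tb.finc, p.e, m);
    if (u < fpe) {                       // photoelectric: full local deposit
      if (!cf.track) sc.add(v, p.w * p.e, hist);
      return;
    } else if (u < fpe + finc) {         // incoherent (Compton)
      double cos_t;
      double eps = sample_kn(p.e, rng, cos_t);
      double e_new = eps * p.e;
      if (!cf.track) sc.add(v, p.w * (p.e - e_new), hist);
      if (e_new < cf.pcut) {             // sub-cutoff: local deposit
        sc.add(v, p.w * e_new, hist);
        return;
      }
      p.e = e_new;
      rotate_dir(p, cos_t, 2.0 * M_PI * rng.u(), rng);
    } else {                             // coherent: deflect, no deposit
      rotate_dir(p, sample_thomson(rng), 2.0 * M_PI * rng.u(), rng);
    }
    is_primary = false;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_primaries(int n, double sid, NumericVector half_field,
                                   NumericVector spec_e, NumericVector spec_cdf,
                                   double seed) {
  NumericMatrix out(n, 8);
  double hx = half_field[0], hy = half_field[1];
  double hd = std::sqrt(hx * hx + hy * hy);
  double cos_lim = sid / std::sqrt(sid * sid + hd * hd);
  int nb = spec_e.size();
  for (int i = 0; i < n; ++i) {
    Rng rng; rng.seed((uint64_t)seed, (uint64_t)i);
    double ux, uy, uz;
    if (hx <= 0 || hy <= 0) {
      ux = 0; uy = 0; uz = -1;
    } else {
      while (true) {
        double c = cos_lim + (1.0 - cos_lim) * rng.u();
        double s = std::sqrt(1.0 - c * c);
        double phi = 2.0 * M_PI * rng.u();
        double px = sid / c * s * std::cos(phi);
        double py = sid / c * s * std::sin(phi);
        if (std::fabs(px) <= hx && std::fabs(py) <= hy) {
          ux = s * std::cos(phi); uy = s * std::sin(phi); uz = -c;
          break;
        }
      }
    }
    double u = rng.u();
    int lo = 0, hi = nb - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    out(i, 0) = 0; out(i, 1) = 0; out(i, 2) = sid;
    out(i, 3) = ux; out(i, 4) = uy; out(i, 5) = uz;
    out(i, 6) = spec_e[lo]; out(i, 7) = 1.0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_transport(IntegerVector labels, IntegerVector dims,
                   NumericVector origin, double dx, double dy,
                   NumericVector z_edges,
                   NumericMatrix mu, NumericMatrix muen,
                   NumericMatrix fpe, NumericMatrix finc, double e_first,
                   double sid, NumericVector half_field,
                   NumericVector spec_e, NumericVector spec_cdf,
                   int n_hist, double seed, double pcut,
                   bool primaries_only, int estimator, int n_split) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = origin[0]; g.oy = origin[1];
  g.dx = dx; g.dy = dy;
  g.ze = z_edges.begin();
  g.lab = labels.begin();
  Tables tb;
  tb.ne = mu.nrow(); tb.nmat = mu.ncol(); tb.e0 = e_first;
  tb.mu = mu.begin(); tb.muen = muen.begin();
  tb.fpe = fpe.begin(); tb.finc = finc.begin();
  Config cf;
  cf.pcut = pcut; cf.primaries_only = primaries_only;
  cf.track = (estimator == 0);
  cf.n_split = n_split;

  Scorer sc(g.nx * g.ny * g.nz);
  double hx = half_field[0], hy = half_field[1];
  double hd = std::sqrt(hx * hx + hy * hy);
  double cos_lim = sid / std::sqrt(sid * sid + hd * hd);
  int nb = spec_e.size();

  for (int h = 0; h < n_hist; ++h) {
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Rng rng; rng.seed((uint64_t)seed, (uint64_t)h);
    Photon p;
    p.x = 0; p.y = 0; p.z = sid; p.w = 1.0;
    if (hx <= 0 || hy <= 0) {
      p.ux = 0; p.uy = 0; p.uz = -1;
    } else {
      while (true) {
        double c = cos_lim + (1.0 - cos_lim) * rng.u();
        double s = std::sqrt(1.0 - c * c);
        double phi = 2.0 * M_PI * rng.u();
        double px = sid / c * s * std::cos(phi);
        double py = sid / c * s * std::sin(phi);
        if (std::fabs(px) <= hx && std::fabs(py) <= hy) {
          p.ux = s * std::cos(phi); p.uy = s * std::sin(phi); p.uz = -c;
          break;
        }
      }
    }
    double u = rng.u();
    int lo = 0, hi = nb - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    p.e = spec_e[lo];
    sc.e_emitted += p.e;

    if (!cf.track && cf.n_split > 1) {
      // interaction splitting of the primary: n_split stratified optical
      // depths along the whole track; descendants keep weight 1/n and are
      // not split further
      Photon probe = p;
      double tau_exit;
      fly(g, tb, probe, 1e30, nullptr, h, false, &tau_exit);
      if (tau_exit > 0) {
        double p_int = 1.0 - std::exp(-tau_exit);
        double strat = rng.u();
        for (int i = 0; i < cf.n_split; ++i) {
          double ui = (i + strat) / cf.n_split;
          if (ui >= p_int) continue;
          double tau_i = -std::log(1.0 - ui);
          Photon sub = p;
          sub.w = p.w / cf.n_split;
          if (!fly(g, tb, sub, tau_i, nullptr, h, false, nullptr)) continue;
          int ix = (int)std::floor((sub.x - g.ox) / g.dx);
          int iy = (int)std::floor((sub.y - g.oy) / g.dy);
          if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny) continue;
          int iz = find_z(g, sub.z);
          int v = g.idx(ix, iy, iz);
          int m = g.lab[v] - 1;
          if (cf.primaries_only) { sc.add(v, sub.w * sub.e, h); continue; }
          double u2 = rng.u();
          double fp = tb.look(tb.fpe, sub.e, m);
          double fi = tb.look(tb.finc, sub.e, m);
          if (u2 < fp) {
            sc.add(v, sub.w * sub.e, h);
          } else if (u2 < fp + fi) {
            double cos_t;
            double eps = sample_kn(sub.e, rng, cos_t);
            double e_new = eps * sub.e;
            sc.add(v, sub.w * (sub.e - e_new), h);
            if (e_new < cf.pcut) {
              sc.add(v, sub.w * e_new, h);
            } else {
              sub.e = e_new;
              rotate_dir(sub, cos_t, 2.0 * M_PI * rng.u(), rng);
              walk(g, tb, sub, rng, sc, h, cf);
            }
          } else {
            rotate_dir(sub, sample_thomson(rng), 2.0 * M_PI * rng.u(), rng);
            walk(g, tb, sub, rng, sc, h, cf);
          }
        }
      }
    } else {
      walk(g, tb, p, rng, sc, h, cf);
    }
  }
  sc.flush();
  return List::create(_["s1"] = NumericVector(sc.s1.begin(), sc.s1.end()),
                      _["s2"] = NumericVector(sc.s2.begin(), sc.s2.end()),
                      _["edep_total"] = sc.edep_total,
                      _["e_emitted"] = sc.e_emitted);
}
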