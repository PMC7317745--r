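// Monte Carlo random-walk diffusion in periodic permeable substrates.
//
// Geometry: either parallel axis-aligned cylinders (periodic in x,y; infinite
// in z) or spheres (periodic in x,y,z). Walkers take fixed-length steps
// sqrt(6*D*dt) in uniformly random 3D directions; membrane crossings within a
// step are resolved by exact ray-object intersection, with transmission
// probability p per encounter and specular reflection otherwise.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-based per-walker RNG (splitmix64): results independent of batching
// ---------------------------------------------------------------------------
static inline uint64_t sm64_next(uint64_t &state) {
  state += 0x9E3779B97f4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double rng_unif(uint64_t &state) {
  // in (0,1)
  return ((sm64_next(state) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline uint64_t stream_seed(int master, int id) {
  uint64_t s = (static_cast<uint64_t>(static_cast<uint32_t>(master)) << 32) ^
               (static_cast<uint64_t>(static_cast<uint32_t>(id)) * 0x9E3779B9ULL + 1ULL);
  // burn-in decorrelates nearby ids
  sm64_next(s); sm64_next(s);
  return s;
}

// ---------------------------------------------------------------------------
// substrate with a uniform cell grid over object centres
// ---------------------------------------------------------------------------
struct Geom {
  int type;                  // 1 = spheres (3D periodic), 2 = cylinders (xy periodic)
  int n;
  double L;
  std::vector<double> cx, cy, cz, r;
  double rmax;
  int m;                     // grid cells per axis (0 => brute force)
  double cell;
  std::vector<std::vector<int> > buckets;
};

static inline double wrap0L(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;       // guard the floating edge case y == L
  if (y < 0) y = 0;
  return y;
}
static inline double minimg(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

static Geom make_geom(const List &sub, double reach) {
  Geom g;
  std::string type = as<std::string>(sub["type"]);
  g.L = as<double>(sub["L"]);
  NumericMatrix cen = sub["centers"];
  g.n = cen.nrow();
  NumericVector rr = sub["radii"];
  if (rr.size() != g.n) stop("radii length must match number of centers");
  g.rmax = 0.0;
  g.cx.resize(g.n); g.cy.resize(g.n); g.cz.resize(g.n); g.r.resize(g.n);
  if (type == "spheres") {
    g.type = 1;
    if (cen.ncol() != 3) stop("sphere centers must be n x 3");
  } else if (type == "cylinders") {
    g.type = 2;
    if (cen.ncol() < 2) stop("cylinder centers must be n x 2");
  } else stop("unknown substrate type");
  for (int i = 0; i < g.n; ++i) {
    g.cx[i] = wrap0L(cen(i, 0), g.L);
    g.cy[i] = wrap0L(cen(i, 1), g.L);
    g.cz[i] = (g.type == 1) ? wrap0L(cen(i, 2), g.L) : 0.0;
    g.r[i] = rr[i];
    if (rr[i] > g.rmax) g.rmax = rr[i];
  }
  // grid: cell size must cover rmax + reach so 3^d neighbourhood suffices
  double need = g.rmax + reach;
  int m = static_cast<int>(std::floor(g.L / (need + 1e-30)));
  if (m < 3 || g.n < 16) { g.m = 0; g.cell = g.L; return g; }
  if (m > 64) m = 64;
  g.m = m;
  g.cell = g.L / m;
  int ncell = (g.type == 1) ? m * m * m : m * m;
  g.buckets.assign(ncell, std::vector<int>());
  for (int i = 0; i < g.n; ++i) {
    int ix = static_cast<int>(g.cx[i] / g.cell); if (ix >= m) ix = m - 1;
    int iy = static_cast<int>(g.cy[i] / g.cell); if (iy >= m) iy = m - 1;
    int idx;
    if (g.type == 1) {
      int iz = static_cast<int>(g.cz[i] / g.cell); if (iz >= m) iz = m - 1;
      idx = ix + m * (iy + m * iz);
    } else idx = ix + m * iy;
    g.buckets[idx].push_back(i);
  }
  return g;
}

// collect candidate object indices near (x,y,z) (wrapped internally)
static inline void candidates(const Geom &g, double x, double y, double z,
                              std::vector<int> &out) {
  out.clear();
  if (g.m == 0) {
    for (int i = 0; i < g.n; ++i) out.push_back(i);
    return;
  }
  int m = g.m;
  double wx = wrap0L(x, g.L), wy = wrap0L(y, g.L);
  int ix = static_cast<int>(wx / g.cell); if (ix >= m) ix = m - 1;
  int iy = static_cast<int>(wy / g.cell); if (iy >= m) iy = m - 1;
  if (g.type == 1) {
    double wz = wrap0L(z, g.L);
    int iz = static_cast<int>(wz / g.cell); if (iz >= m) iz = m - 1;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int jx = (ix + a + m) % m, jy = (iy + b + m) % m, jz = (iz + c + m) % m;
          const std::vector<int> &v = g.buckets[jx + m * (jy + m * jz)];
          out.insert(out.end(), v.begin(), v.end());
        }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        int jx = (ix + a + m) % m, jy = (iy + b + m) % m;
        const std::vector<int> &v = g.buckets[jx + m * jy];
        out.insert(out.end(), v.begin(), v.end());
      }
  }
}

// compartment of a point: 0 extracellular, 1..n object index
static int locate_point(const Geom &g, double x, double y, double z,
                        std::vector<int> &scratch) {
  candidates(g, x, y, z, scratch);
  double wx = wrap0L(x, g.L), wy = wrap0L(y, g.L);
  double wz = (g.type == 1) ? wrap0L(z, g.L) : 0.0;
  for (size_t k = 0; k < scratch.size(); ++k) {
    int j = scratch[k];
    double ox = minimg(g.cx[j] - wx, g.L);
    double oy = minimg(g.cy[j] - wy, g.L);
    double d2;
    if (g.type == 1) {
      double oz = minimg(g.cz[j] - wz, g.L);
      d2 = ox * ox + oy * oy + oz * oz;
    } else d2 = ox * ox + oy * oy;
    if (d2 < g.r[j] * g.r[j]) return j + 1;
  }
  return 0;
}

// earliest membrane crossing along p + t*d, t in (tmin, s]; returns object
// index (0-based) or -1; fills t, outward normal at hit
struct Hit { double t, nx, ny, nz; int idx; };

static bool first_hit(const Geom &g, double px, double py, double pz,
                      double dx, double dy, double dz, double s,
                      std::vector<int> &scratch, Hit &hit) {
  // candidates around segment midpoint; grid reach covers rmax + step
  candidates(g, px + 0.5 * s * dx, py + 0.5 * s * dy, pz + 0.5 * s * dz, scratch);
  double wx = wrap0L(px, g.L), wy = wrap0L(py, g.L);
  double wz = (g.type == 1) ? wrap0L(pz, g.L) : 0.0;
  double best = s * (1.0 + 1e-12);
  int bi = -1;
  double bx = 0, by = 0, bz = 0;
  const double tmin = 1e-12;   // absolute metres along the segment
  for (size_t k = 0; k < scratch.size(); ++k) {
    int j = scratch[k];
    double ox = minimg(g.cx[j] - wx, g.L);
    double oy = minimg(g.cy[j] - wy, g.L);
    double t1, t2;
    if (g.type == 1) {
      double oz = minimg(g.cz[j] - wz, g.L);
      double b = dx * ox + dy * oy + dz * oz;       // |d| = 1
      double c = ox * ox + oy * oy + oz * oz - g.r[j] * g.r[j];
      double disc = b * b - c;
      if (disc < 0) continue;
      double sq = std::sqrt(disc);
      t1 = b - sq; t2 = b + sq;
    } else {
      double a = dx * dx + dy * dy;
      if (a < 1e-300) continue;
      double b = dx * ox + dy * oy;
      double c = ox * ox + oy * oy - g.r[j] * g.r[j];
      double disc = b * b - a * c;
      if (disc < 0) continue;
      double sq = std::sqrt(disc);
      t1 = (b - sq) / a; t2 = (b + sq) / a;
    }
    double t = std::numeric_limits<double>::infinity();
    if (t1 > tmin && t1 <= best) t = t1;
    else if (t2 > tmin && t2 <= best) t = t2;
    if (t < best) {
      best = t; bi = j;
      bx = ox; by = oy; bz = (g.type == 1) ? minimg(g.cz[j] - wz, g.L) : 0.0;
    }
  }
  if (bi < 0) return false;
  hit.t = best; hit.idx = bi;
  // outward normal: hit point minus centre
  double hx = best * dx - bx, hy = best * dy - by;
  double hz = (g.type == 1) ? (best * dz - bz) : 0.0;
  double nn = std::sqrt(hx * hx + hy * hy + hz * hz);
  if (nn < 1e-300) { hx = 1; hy = 0; hz = 0; nn = 1; }
  hit.nx = hx / nn; hit.ny = hy / nn; hit.nz = hz / nn;
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(List substrate, NumericMatrix points) {
  Geom g = make_geom(substrate, 0.0);
  std::vector<int> scratch;
  int np = points.nrow();
  IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    double z = (points.ncol() >= 3) ? points(i, 2) : 0.0;
    out[i] = locate_point(g, points(i, 0), points(i, 1), z, scratch);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_first_intersection(List substrate, NumericMatrix starts, NumericMatrix ends) {
  int ns = starts.nrow();
  NumericVector tt(ns), nx(ns), ny(ns), nz(ns);
  IntegerVector idx(ns);
  double rmax_seg = 0;
  for (int i = 0; i < ns; ++i) {
    double dx = ends(i, 0) - starts(i, 0), dy = ends(i, 1) - starts(i, 1);
    double dz = (starts.ncol() >= 3) ? ends(i, 2) - starts(i, 2) : 0.0;
    double s = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (s > rmax_seg) rmax_seg = s;
  }
  Geom g = make_geom(substrate, rmax_seg);
  std::vector<int> scratch;
  Hit h;
  for (int i = 0; i < ns; ++i) {
    double px = starts(i, 0), py = starts(i, 1);
    double pz = (starts.ncol() >= 3) ? starts(i, 2) : 0.0;
    double dx = ends(i, 0) - px, dy = ends(i, 1) - py;
    double dz = (starts.ncol() >= 3) ? ends(i, 2) - pz : 0.0;
    double s = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (s <= 0) stop("zero-length segment");
    dx /= s; dy /= s; dz /= s;
    if (first_hit(g, px, py, pz, dx, dy, dz, s, scratch, h)) {
      tt[i] = h.t; idx[i] = h.idx + 1;
      nx[i] = h.nx; ny[i] = h.ny; nz[i] = h.nz;
    } else {
      tt[i] = NA_REAL; idx[i] = 0;
      nx[i] = NA_REAL; ny[i] = NA_REAL; nz[i] = NA_REAL;
    }
  }
  return List::create(_["distance"] = tt, _["object"] = idx,
                      _["nx"] = nx, _["ny"] = ny, _["nz"] = nz);
}

// ---------------------------------------------------------------------------
// the walker engine
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(List substrate, int n_walkers, int n_steps, double dt, double D,
                  double p_transit, int seed, NumericMatrix directions,
                  bool store_proj, bool store_positions, int label_stride,
                  Nullable<NumericMatrix> waveforms) {
  if (n_walkers < 1 || n_steps < 1) stop("need at least one walker and one step");
  if (dt <= 0 || D <= 0) stop("dt and D must be positive");
  if (p_transit < 0 || p_transit > 1) stop("transit probability must lie in [0,1]");
  const double step = std::sqrt(6.0 * D * dt);
  const double nudge = 1e-12;          // metres off the surface after an event
  const int MAXB = 1000;               // membrane interactions per step

  bool empty_sub = false;
  Geom g;
  {
    NumericMatrix cen = substrate["centers"];
    if (cen.nrow() == 0) empty_sub = true; else g = make_geom(substrate, step);
  }
  // one or more measurement directions; projections for direction d occupy
  // proj columns [d * n_walkers, (d + 1) * n_walkers)
  const int n_dir = directions.nrow();
  if (n_dir < 1 || directions.ncol() < 3) stop("directions must be n x 3");
  std::vector<double> ux(n_dir), uy(n_dir), uz(n_dir);
  for (int d = 0; d < n_dir; ++d) {
    double a = directions(d, 0), b = directions(d, 1), c = directions(d, 2);
    double un = std::sqrt(a * a + b * b + c * c);
    if (un <= 0) stop("direction must be non-zero");
    ux[d] = a / un; uy[d] = b / un; uz[d] = c / un;
  }

  // label checkpoints
  if (label_stride < 1) label_stride = 1;
  std::vector<int> cksteps;
  for (int k = 0; k <= n_steps; k += label_stride) cksteps.push_back(k);
  if (cksteps.back() != n_steps) cksteps.push_back(n_steps);
  int nck = cksteps.size();

  NumericMatrix proj;
  if (store_proj) {
    if (static_cast<double>(n_steps + 1) * n_walkers * n_dir > 4e8)
      stop("projection storage too large; reduce walkers, steps or directions");
    proj = NumericMatrix(n_steps + 1, n_walkers * n_dir);
  }
  NumericVector positions;
  if (store_positions) {
    if (static_cast<double>(n_steps + 1) * 3.0 * n_walkers > 6e7)
      stop("full position storage only supported for small runs");
    positions = NumericVector(Dimension(n_steps + 1, 3, n_walkers));
  }
  NumericMatrix phase;
  int n_wave = 0;
  NumericMatrix W;
  if (waveforms.isNotNull()) {
    W = NumericMatrix(waveforms);
    if (W.nrow() != n_steps) stop("waveforms must have n_steps rows");
    n_wave = W.ncol();
    phase = NumericMatrix(n_walkers, n_wave);
  }

  NumericMatrix disp(n_walkers, 3), init(n_walkers, 3);
  IntegerMatrix labels(nck, n_walkers);
  IntegerVector crossings(n_walkers);

  std::vector<int> scratch;
  Hit h;
  const double L = empty_sub ? 1.0 : g.L;

  for (int w = 0; w < n_walkers; ++w) {
    uint64_t rs = stream_seed(seed, w);
    double px = L * rng_unif(rs), py = L * rng_unif(rs), pz = L * rng_unif(rs);
    init(w, 0) = px; init(w, 1) = py; init(w, 2) = pz;
    double sx = 0, sy = 0, sz = 0;  // cumulative (unwrapped) displacement
    int label = empty_sub ? 0 : locate_point(g, px, py, pz, scratch);
    int ck = 0, ncross = 0;
    labels(ck++, w) = label;
    std::vector<double> pr0(n_dir);
    for (int d = 0; d < n_dir; ++d) {
      pr0[d] = px * ux[d] + py * uy[d] + pz * uz[d];
      if (store_proj) proj(0, w + n_walkers * d) = pr0[d];
    }
    if (store_positions) {
      positions[0 + (n_steps + 1) * (0 + 3 * w)] = px;
      positions[0 + (n_steps + 1) * (1 + 3 * w)] = py;
      positions[0 + (n_steps + 1) * (2 + 3 * w)] = pz;
    }
    for (int k = 0; k < n_steps; ++k) {
      if (n_wave > 0) {
        // on-the-fly accumulation uses the first direction
        double cur_proj = pr0[0] + sx * ux[0] + sy * uy[0] + sz * uz[0];
        for (int q = 0; q < n_wave; ++q) phase(w, q) += W(k, q) * cur_proj;
      }
      // random direction uniform on the sphere
      double zz = 2.0 * rng_unif(rs) - 1.0;
      double ph = 6.283185307179586 * rng_unif(rs);
      double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
      double dx = rr * std::cos(ph), dy = rr * std::sin(ph), dz = zz;
      double remaining = step;
      if (empty_sub) {
        sx += dx * remaining; sy += dy * remaining; sz += dz * remaining;
        px += dx * remaining; py += dy * remaining; pz += dz * remaining;
      } else {
        int bounce = 0;
        for (; bounce < MAXB && remaining > 0; ++bounce) {
          if (!first_hit(g, px, py, pz, dx, dy, dz, remaining, scratch, h)) {
            px += dx * remaining; py += dy * remaining; pz += dz * remaining;
            sx += dx * remaining; sy += dy * remaining; sz += dz * remaining;
            remaining = 0;
            break;
          }
          // advance to the membrane
          px += dx * h.t; py += dy * h.t; pz += dz * h.t;
          sx += dx * h.t; sy += dy * h.t; sz += dz * h.t;
          remaining -= h.t;
          if (rng_unif(rs) < p_transit) {
            // transmit: keep direction, flip compartment
            label = (label == h.idx + 1) ? 0 : (h.idx + 1);
            ++ncross;
          } else {
            // specular reflection about the surface normal
            double dn = dx * h.nx + dy * h.ny + dz * h.nz;
            dx -= 2.0 * dn * h.nx; dy -= 2.0 * dn * h.ny; dz -= 2.0 * dn * h.nz;
          }
          // nudge off the surface along the (possibly new) direction
          px += dx * nudge; py += dy * nudge; pz += dz * nudge;
          sx += dx * nudge; sy += dy * nudge; sz += dz * nudge;
        }
        if (bounce >= MAXB)
          stop("walker %d exceeded the membrane-interaction budget at step %d", w + 1, k + 1);
        // keep the wrapped coordinate bounded
        px = wrap0L(px, g.L); py = wrap0L(py, g.L);
        if (g.type == 1) pz = wrap0L(pz, g.L);
      }
      if (store_proj)
        for (int d = 0; d < n_dir; ++d)
          proj(k + 1, w + n_walkers * d) =
            pr0[d] + sx * ux[d] + sy * uy[d] + sz * uz[d];
      if (store_positions) {
        positions[(k + 1) + (n_steps + 1) * (0 + 3 * w)] = init(w, 0) + sx;
        positions[(k + 1) + (n_steps + 1) * (1 + 3 * w)] = init(w, 1) + sy;
        positions[(k + 1) + (n_steps + 1) * (2 + 3 * w)] = init(w, 2) + sz;
      }
      if (ck < nck && cksteps[ck] == k + 1) labels(ck++, w) = label;
    }
    disp(w, 0) = sx; disp(w, 1) = sy; disp(w, 2) = sz;
    crossings[w] = ncross;
    if ((w & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
    _["displacement"] = disp, _["initial"] = init,
    _["labels"] = labels, _["label_steps"] = wrap(cksteps),
    _["crossings"] = crossings);
  if (store_proj) out["proj"] = proj;
  if (store_positions) out["positions"] = positions;
  if (n_wave > 0) out["phase"] = phase;
  return out;
}

// ---------------------------------------------------------------------------
// dense periodic sphere packing: staged radius growth + overlap relaxation
// ---------------------------------------------------------------------------

// one Gauss-Seidel sweep separating overlapping pairs; returns overlap count
static int relax_sweep(std::vector<double> &x, std::vector<double> &y,
                       std::vector<double> &z, int n, double L, double rc,
                       double overpush, uint64_t &rs) {
  double dmin = 2.0 * rc;
  int m = static_cast<int>(std::floor(L / dmin));
  if (m > 48) m = 48;
  bool brute = (m < 3);
  std::vector<std::vector<int> > buckets;
  double cell = 0;
  if (!brute) {
    cell = L / m;
    buckets.assign(m * m * m, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      int ix = std::min(m - 1, static_cast<int>(x[i] / cell));
      int iy = std::min(m - 1, static_cast<int>(y[i] / cell));
      int iz = std::min(m - 1, static_cast<int>(z[i] / cell));
      buckets[ix + m * (iy + m * iz)].push_back(i);
    }
  }
  int nov = 0;
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    if (brute) { for (int j = 0; j < n; ++j) if (j != i) cand.push_back(j); }
    else {
      int ix = std::min(m - 1, static_cast<int>(x[i] / cell));
      int iy = std::min(m - 1, static_cast<int>(y[i] / cell));
      int iz = std::min(m - 1, static_cast<int>(z[i] / cell));
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            const std::vector<int> &v =
              buckets[((ix + a + m) % m) + m * (((iy + b + m) % m) + m * ((iz + c + m) % m))];
            for (size_t q = 0; q < v.size(); ++q) if (v[q] != i) cand.push_back(v[q]);
          }
    }
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      double dx = minimg(x[j] - x[i], L);
      double dy = minimg(y[j] - y[i], L);
      double dz = minimg(z[j] - z[i], L);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < dmin) {
        ++nov;
        double push;
        if (d < 1e-15) {
          double zz = 2.0 * rng_unif(rs) - 1.0;
          double ph = 6.283185307179586 * rng_unif(rs);
          double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
          dx = rr * std::cos(ph); dy = rr * std::sin(ph); dz = zz; d = 1.0;
          push = dmin * 0.5;
        } else push = 0.5 * (dmin - d) * overpush;
        double fx = dx / d * push, fy = dy / d * push, fz = dz / d * push;
        x[i] = wrap0L(x[i] - fx, L); y[i] = wrap0L(y[i] - fy, L); z[i] = wrap0L(z[i] - fz, L);
        x[j] = wrap0L(x[j] + fx, L); y[j] = wrap0L(y[j] + fy, L); z[j] = wrap0L(z[j] + fz, L);
      }
    }
  }
  return nov;
}

// [[Rcpp::export]]
List cpp_pack_spheres(int n, double radius, double L, int seed,
                      int n_stages, int max_sweeps) {
  if (n < 1) stop("need at least one sphere");
  if (2.0 * radius > L) stop("sphere diameter exceeds the periodic box");
  uint64_t rs = stream_seed(seed, 7919);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = L * rng_unif(rs); y[i] = L * rng_unif(rs); z[i] = L * rng_unif(rs);
  }
  double r_ok = 0.0;
  double f0 = 0.55;  // starting radius fraction; RSA-like densities relax instantly
  for (int st = 0; st <= n_stages; ++st) {
    double rc = radius * (f0 + (1.0 - f0) * st / n_stages);
    bool ok = false;
    // symmetric over-push (separate to ~2*dmin - d) escapes the pairwise
    // livelock minimal pushes fall into; jitter kicks break rare residual
    // cycles near the jamming density
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      int nov = relax_sweep(x, y, z, n, L, rc, 2.0, rs);
      if (nov == 0) { ok = true; break; }
      if (sweep > 0 && sweep % 500 == 0) {
        double kick = 0.02 * rc;
        for (int i = 0; i < n; ++i) {
          x[i] = wrap0L(x[i] + kick * (2.0 * rng_unif(rs) - 1.0), L);
          y[i] = wrap0L(y[i] + kick * (2.0 * rng_unif(rs) - 1.0), L);
          z[i] = wrap0L(z[i] + kick * (2.0 * rng_unif(rs) - 1.0), L);
        }
      }
      if ((sweep & 255) == 0) Rcpp::checkUserInterrupt();
    }
    if (!ok) {
      double phi = n * (4.0 / 3.0) * M_PI * r_ok * r_ok * r_ok / (L * L * L);
      stop("sphere densification stalled: achieved packing fraction %.4f", phi);
    }
    r_ok = rc;
  }
  NumericMatrix cen(n, 3);
  for (int i = 0; i < n; ++i) { cen(i, 0) = x[i]; cen(i, 1) = y[i]; cen(i, 2) = z[i]; }
  return List::create(_["centers"] = cen, _["radius"] = radius);
}
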