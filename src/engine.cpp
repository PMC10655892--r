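// Underdamped Langevin engine for the bead-spring chromosome model.
// Units: sigma = kBT = m = 1. Species codes: 1 chromatin, 2 loop anchor,
// 3 bridge. Pair kinds: 0 none, 1 soft (bounded, strand-crossing allowed),
// 2 truncated/shifted Lennard-Jones.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---- counter-based RNG: one stream keyed by (seed, step, particle) ----
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t x) {
  return ((splitmix64(x) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
// three standard normals for particle i at integration step t
static inline void gauss3(uint64_t seed, uint64_t t, uint64_t i, double* g) {
  uint64_t base = splitmix64(seed ^ splitmix64(t * 0x9E3779B97F4A7C15ULL + i));
  uint64_t a = splitmix64(base + 1), b = splitmix64(base + 2);
  const double inv32 = 1.0 / 4294967296.0;
  double u1 = ((a >> 32) + 0.5) * inv32, u2 = ((a & 0xFFFFFFFFULL) + 0.5) * inv32;
  double u3 = ((b >> 32) + 0.5) * inv32, u4 = ((b & 0xFFFFFFFFULL) + 0.5) * inv32;
  double r1 = std::sqrt(-2.0 * std::log(u1));
  double r2 = std::sqrt(-2.0 * std::log(u3));
  g[0] = r1 * std::cos(2.0 * PI_ * u2);
  g[1] = r1 * std::sin(2.0 * PI_ * u2);
  g[2] = r2 * std::cos(2.0 * PI_ * u4);
}

struct PairTable {
  int kind[4][4];        // 1-based species
  double eps[4][4];      // soft amplitude or LJ epsilon (kBT)
  double cut[4][4];
  double shift[4][4];    // energy shift so U(cut) = 0 where requested
  double cut2[4][4];
  double rmax;           // largest cutoff
};

static PairTable make_pair_table(IntegerMatrix kindM, NumericMatrix epsM,
                                 NumericMatrix cutM, IntegerMatrix shiftM) {
  PairTable pt;
  pt.rmax = 0.0;
  for (int a = 1; a <= 3; ++a) for (int b = 1; b <= 3; ++b) {
    pt.kind[a][b] = kindM(a - 1, b - 1);
    pt.eps[a][b]  = epsM(a - 1, b - 1);
    pt.cut[a][b]  = cutM(a - 1, b - 1);
    pt.shift[a][b] = 0.0;
    if (pt.kind[a][b] == 2 && shiftM(a - 1, b - 1)) {
      double rc = pt.cut[a][b];
      double sr6 = 1.0 / (rc * rc * rc * rc * rc * rc);
      pt.shift[a][b] = 4.0 * pt.eps[a][b] * (sr6 * sr6 - sr6);
    }
    pt.cut2[a][b] = (pt.kind[a][b] != 0) ?
      pt.cut[a][b] * pt.cut[a][b] : 0.0;
    if (pt.cut[a][b] > pt.rmax) pt.rmax = pt.cut[a][b];
  }
  return pt;
}

// pairwise energy/scalar force; fscal multiplies the separation vector r_i - r_j
static inline void pair_eval(int kind, double eps, double rc, double shift,
                             double r2, double& u, double& fscal) {
  u = 0.0; fscal = 0.0;
  if (kind == 1) {                       // soft: A(1 + cos(pi r / rc))
    double r = std::sqrt(r2);
    if (r >= rc) return;
    u = eps * (1.0 + std::cos(PI_ * r / rc));
    if (r > 1e-12) fscal = eps * PI_ / rc * std::sin(PI_ * r / rc) / r;
  } else if (kind == 2) {                // LJ, truncated (optionally shifted)
    if (r2 >= rc * rc) return;
    double sr2 = 1.0 / r2, sr6 = sr2 * sr2 * sr2;
    u = 4.0 * eps * (sr6 * sr6 - sr6) - shift;
    fscal = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * sr2;
  }
}

struct System {
  int n;
  std::vector<double> x;                 // wrapped positions, 3n
  std::vector<int> img;                  // image counters, 3n
  double L;                              // cubic box side (<=0: open boundary)
  std::vector<int> species;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bK, br0;
  // angles
  std::vector<int> a1, a2, a3; std::vector<double> aK;
  PairTable pt;
  // exclusions (directly bonded pairs), per particle, sorted
  std::vector<std::vector<int>> excl;
  // verlet list; per-species-pair list radii (cutoff + skin)
  double rpair[4][4];
  double skin, rlist;
  std::vector<int> nbr, nstart;
  std::vector<double> xref;

  inline void mindelta(int i, int j, double* d) const {
    double h = 0.5 * L;
    for (int k = 0; k < 3; ++k) {
      d[k] = x[3 * i + k] - x[3 * j + k];
      if (L > 0) {
        if (d[k] > h) d[k] -= L; else if (d[k] < -h) d[k] += L;
      }
    }
  }
  inline bool excluded(int i, int j) const {
    const std::vector<int>& e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }

  void build_list() {
    nstart.assign(n + 1, 0);
    nbr.clear();
    int nc = 0;
    if (L > 0) nc = (int)std::floor(L / rlist);
    if (nc >= 3) {
      // cells of size ~rlist, spatially hashed into an O(n) bucket table:
      // large dilute boxes stay cheap, hash collisions only add candidates
      double cell = L / nc;
      int M = 64;
      while (M < 4 * n) M <<= 1;
      std::vector<int> head(M, -1), nxt(n, -1);
      std::vector<int> cx(n), cy(n), cz(n);
      auto bucket = [&](int ix, int iy, int iz) {
        uint32_t h = (uint32_t)ix * 73856093u ^ (uint32_t)iy * 19349663u ^
                     (uint32_t)iz * 83492791u;
        return (int)(h & (uint32_t)(M - 1));
      };
      for (int i = 0; i < n; ++i) {
        int ix = (int)std::floor(x[3*i] / cell);   ix = ((ix % nc) + nc) % nc;
        int iy = (int)std::floor(x[3*i+1] / cell); iy = ((iy % nc) + nc) % nc;
        int iz = (int)std::floor(x[3*i+2] / cell); iz = ((iz % nc) + nc) % nc;
        cx[i] = ix; cy[i] = iy; cz[i] = iz;
        int c = bucket(ix, iy, iz);
        nxt[i] = head[c]; head[c] = i;
      }
      double d[3];
      int seen[27];
      for (int i = 0; i < n; ++i) {
        nstart[i] = (int)nbr.size();
        int si = species[i];
        int nseen = 0;
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int ix = (cx[i] + dx + nc) % nc, iy = (cy[i] + dy + nc) % nc,
              iz = (cz[i] + dz + nc) % nc;
          int b = bucket(ix, iy, iz);
          bool dup = false;           // colliding buckets: scan only once
          for (int q = 0; q < nseen; ++q) if (seen[q] == b) { dup = true; break; }
          if (dup) continue;
          seen[nseen++] = b;
          for (int j = head[b]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double rl = rpair[si][species[j]];
            mindelta(i, j, d);
            if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < rl * rl &&
                !excluded(i, j))
              nbr.push_back(j);
          }
        }
      }
      nstart[n] = (int)nbr.size();
    } else {
      double d[3];
      for (int i = 0; i < n; ++i) {
        nstart[i] = (int)nbr.size();
        int si = species[i];
        for (int j = i + 1; j < n; ++j) {
          double rl = rpair[si][species[j]];
          mindelta(i, j, d);
          if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < rl * rl &&
              !excluded(i, j))
            nbr.push_back(j);
        }
      }
      nstart[n] = (int)nbr.size();
    }
    xref = x;
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = x[i] - xref[i], dy = x[i+1] - xref[i+1], dz = x[i+2] - xref[i+2];
      if (L > 0) {
        dx -= L * std::round(dx / L); dy -= L * std::round(dy / L);
        dz -= L * std::round(dz / L);
      }
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }

  // conservative forces + energy decomposition
  void forces(std::vector<double>& f, double* e) {
    std::fill(f.begin(), f.end(), 0.0);
    e[0] = e[1] = e[2] = 0.0;            // pair, bond, angle
    double d[3];
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      mindelta(i, j, d);
      double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      double dr = r - br0[b];
      e[1] += bK[b] * dr * dr;
      double fs = (r > 1e-12) ? -2.0 * bK[b] * dr / r : 0.0;
      for (int k = 0; k < 3; ++k) { f[3*i+k] += fs * d[k]; f[3*j+k] -= fs * d[k]; }
    }
    // angles: Kratky-Porod U = K (1 + cos phi), phi at the central bead
    double da[3], db[3];
    for (size_t a = 0; a < a1.size(); ++a) {
      int i = a1[a], j = a2[a], k = a3[a];
      mindelta(i, j, da);
      mindelta(k, j, db);
      double ra2 = da[0]*da[0]+da[1]*da[1]+da[2]*da[2];
      double rb2 = db[0]*db[0]+db[1]*db[1]+db[2]*db[2];
      double ra = std::sqrt(ra2), rb = std::sqrt(rb2);
      if (ra < 1e-12 || rb < 1e-12) continue;
      double dot = da[0]*db[0] + da[1]*db[1] + da[2]*db[2];
      double c = dot / (ra * rb);
      if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
      e[2] += aK[a] * (1.0 + c);
      // F = -K * grad(cos phi)
      for (int q = 0; q < 3; ++q) {
        double g1 = db[q] / (ra * rb) - c * da[q] / ra2;
        double g3 = da[q] / (ra * rb) - c * db[q] / rb2;
        f[3*i+q] += -aK[a] * g1;
        f[3*k+q] += -aK[a] * g3;
        f[3*j+q] +=  aK[a] * (g1 + g3);
      }
    }
    // non-bonded pairs (exclusions already filtered out of the list)
    double halfL = 0.5 * L;
    for (int i = 0; i < n; ++i) {
      int si = species[i];
      double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
      double fxi = 0, fyi = 0, fzi = 0;
      for (int q = nstart[i]; q < nstart[i + 1]; ++q) {
        int j = nbr[q];
        double dx = xi - x[3*j], dy = yi - x[3*j+1], dz = zi - x[3*j+2];
        if (L > 0) {
          if (dx > halfL) dx -= L; else if (dx < -halfL) dx += L;
          if (dy > halfL) dy -= L; else if (dy < -halfL) dy += L;
          if (dz > halfL) dz -= L; else if (dz < -halfL) dz += L;
        }
        double r2 = dx*dx + dy*dy + dz*dz;
        int sj = species[j];
        if (r2 >= pt.cut2[si][sj]) continue;
        double u, fs;
        pair_eval(pt.kind[si][sj], pt.eps[si][sj], pt.cut[si][sj],
                  pt.shift[si][sj], r2, u, fs);
        e[0] += u;
        fxi += fs * dx; fyi += fs * dy; fzi += fs * dz;
        f[3*j]   -= fs * dx; f[3*j+1] -= fs * dy; f[3*j+2] -= fs * dz;
      }
      f[3*i] += fxi; f[3*i+1] += fyi; f[3*i+2] += fzi;
    }
  }
};

static System make_system(NumericMatrix pos, IntegerVector species, double box,
                          IntegerMatrix bonds, NumericVector bondK, NumericVector bondR0,
                          IntegerMatrix angles, NumericVector angleK,
                          IntegerMatrix kindM, NumericMatrix epsM,
                          NumericMatrix cutM, IntegerMatrix shiftM, double skin) {
  System sys;
  sys.n = pos.nrow();
  sys.L = box;
  sys.x.resize(3 * sys.n);
  sys.img.assign(3 * sys.n, 0);
  for (int i = 0; i < sys.n; ++i) for (int k = 0; k < 3; ++k) {
    double xi = pos(i, k);
    if (box > 0) {
      int im = (int)std::floor(xi / box);
      sys.img[3*i+k] = im;
      xi -= im * box;
    }
    sys.x[3*i+k] = xi;
  }
  sys.species.assign(species.begin(), species.end());
  int nb = bonds.nrow();
  sys.bi.resize(nb); sys.bj.resize(nb);
  sys.bK.assign(bondK.begin(), bondK.end());
  sys.br0.assign(bondR0.begin(), bondR0.end());
  sys.excl.assign(sys.n, {});
  for (int b = 0; b < nb; ++b) {
    sys.bi[b] = bonds(b, 0) - 1; sys.bj[b] = bonds(b, 1) - 1;
    sys.excl[sys.bi[b]].push_back(sys.bj[b]);
    sys.excl[sys.bj[b]].push_back(sys.bi[b]);
  }
  for (int i = 0; i < sys.n; ++i) std::sort(sys.excl[i].begin(), sys.excl[i].end());
  int na = angles.nrow();
  sys.a1.resize(na); sys.a2.resize(na); sys.a3.resize(na);
  for (int a = 0; a < na; ++a) {
    sys.a1[a] = angles(a, 0) - 1; sys.a2[a] = angles(a, 1) - 1;
    sys.a3[a] = angles(a, 2) - 1;
  }
  sys.aK.assign(angleK.begin(), angleK.end());
  sys.pt = make_pair_table(kindM, epsM, cutM, shiftM);
  sys.skin = skin;
  sys.rlist = (sys.pt.rmax > 0 ? sys.pt.rmax : 1.0) + skin;
  for (int a = 1; a <= 3; ++a) for (int b = 1; b <= 3; ++b)
    sys.rpair[a][b] = (sys.pt.cut[a][b] > 0) ?
      sys.pt.cut[a][b] + skin : 0.0;
  if (box > 0 && sys.rlist > box / 2.0)
    stop("neighbour cutoff + skin exceeds half the box side (minimum-image violation)");
  sys.build_list();
  return sys;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                double box, IntegerMatrix bonds, NumericVector bondK,
                NumericVector bondR0, IntegerMatrix angles, NumericVector angleK,
                IntegerMatrix kindM, NumericMatrix epsM, NumericMatrix cutM,
                IntegerMatrix shiftM, int nsteps, double dt, double gamma,
                double kT, int seed, double stepOffset, int stride,
                int pullA, int pullB, double pullF, double skin) {
  System sys = make_system(pos, species, box, bonds, bondK, bondR0, angles,
                           angleK, kindM, epsM, cutM, shiftM, skin);
  int n = sys.n;
  std::vector<double> v(3 * n), f(3 * n), fl(3 * n, 0.0);
  for (int i = 0; i < n; ++i) for (int k = 0; k < 3; ++k) v[3*i+k] = vel(i, k);
  double e[3];
  double noise = (gamma > 0) ? std::sqrt(2.0 * kT * gamma / dt) : 0.0;
  uint64_t useed = (uint64_t)seed;

  int nframes = (stride > 0) ? nsteps / stride : 0;
  NumericMatrix frames(nframes * (stride > 0 ? n : 0), 3);
  NumericVector ftimes(nframes);
  int fidx = 0;
  double g[3];

  sys.forces(f, e);
  // external pulling + Langevin pieces enter the stored force
  auto add_external = [&](uint64_t step) {
    if (pullA >= 1 && pullB >= 1 && pullF != 0.0) {
      int a = pullA - 1, b = pullB - 1;
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = (sys.x[3*a+k] + sys.img[3*a+k] * sys.L) -
               (sys.x[3*b+k] + sys.img[3*b+k] * sys.L);
      double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      if (r > 1e-12) for (int k = 0; k < 3; ++k) {
        f[3*a+k] += pullF * d[k] / r;
        f[3*b+k] -= pullF * d[k] / r;
      }
    }
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        gauss3(useed, step, (uint64_t)i, g);
        for (int k = 0; k < 3; ++k)
          f[3*i+k] += -gamma * v[3*i+k] + noise * g[k];
      }
    }
  };
  add_external((uint64_t)std::llround(stepOffset));

  for (int s = 0; s < nsteps; ++s) {
    uint64_t step = (uint64_t)std::llround(stepOffset) + (uint64_t)s + 1ULL;
    for (int q = 0; q < 3 * n; ++q) v[q] += 0.5 * dt * f[q];
    for (int i = 0; i < n; ++i) for (int k = 0; k < 3; ++k) {
      double& xi = sys.x[3*i+k];
      xi += dt * v[3*i+k];
      if (sys.L > 0) {
        if (xi >= sys.L) { xi -= sys.L; sys.img[3*i+k] += 1; }
        else if (xi < 0) { xi += sys.L; sys.img[3*i+k] -= 1; }
      }
    }
    if (sys.need_rebuild()) sys.build_list();
    sys.forces(f, e);
    add_external(step);
    for (int q = 0; q < 3 * n; ++q) v[q] += 0.5 * dt * f[q];

    if (stride > 0 && (s + 1) % stride == 0) {
      for (int i = 0; i < n; ++i) for (int k = 0; k < 3; ++k)
        frames(fidx * n + i, k) = sys.x[3*i+k] + sys.img[3*i+k] * sys.L;
      ftimes[fidx] = (stepOffset + s + 1) * dt;
      ++fidx;
    }
    if ((s & 1023) == 0) {
      for (int q = 0; q < 3 * n; ++q)
        if (!std::isfinite(sys.x[q]))
          stop("non-finite coordinate at step %d (particle %d): integration blew up",
               s, q / 3 + 1);
    }
  }

  NumericMatrix outp(n, 3), outv(n, 3);
  for (int i = 0; i < n; ++i) for (int k = 0; k < 3; ++k) {
    outp(i, k) = sys.x[3*i+k] + (sys.L > 0 ? sys.img[3*i+k] * sys.L : 0.0);
    outv(i, k) = v[3*i+k];
  }
  sys.forces(f, e);
  double ke = 0.0;
  for (int q = 0; q < 3 * n; ++q) ke += 0.5 * v[q] * v[q];
  return List::create(_["positions"] = outp, _["velocities"] = outv,
                      _["frames"] = frames, _["frame_times"] = ftimes,
                      _["n_frames"] = fidx,
                      _["energy"] = NumericVector::create(
                        _["pair"] = e[0], _["bond"] = e[1], _["angle"] = e[2],
                        _["kinetic"] = ke),
                      _["step_offset"] = stepOffset + nsteps);
}

// [[Rcpp::export(name = ".engine_eval")]]
List engine_eval(NumericMatrix pos, IntegerVector species, double box,
                 IntegerMatrix bonds, NumericVector bondK, NumericVector bondR0,
                 IntegerMatrix angles, NumericVector angleK, IntegerMatrix kindM,
                 NumericMatrix epsM, NumericMatrix cutM, IntegerMatrix shiftM,
                 double skin) {
  System sys = make_system(pos, species, box, bonds, bondK, bondR0, angles,
                           angleK, kindM, epsM, cutM, shiftM, skin);
  std::vector<double> f(3 * sys.n);
  double e[3];
  sys.forces(f, e);
  NumericMatrix outf(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) for (int k = 0; k < 3; ++k)
    outf(i, k) = f[3*i+k];
  return List::create(
    _["energy"] = NumericVector::create(_["pair"] = e[0], _["bond"] = e[1],
                                        _["angle"] = e[2]),
    _["forces"] = outf);
}

// [[Rcpp::export(name = ".neighbor_pairs")]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, double box, double cutoff,
                                 double skin) {
  int n = pos.nrow();
  IntegerMatrix bonds(0, 2);
  NumericVector z(0);
  IntegerMatrix angles(0, 3);
  IntegerMatrix kindM(3, 3); NumericMatrix epsM(3, 3), cutM(3, 3);
  IntegerMatrix shiftM(3, 3);
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) cutM(a, b) = cutoff;
  IntegerVector sp(n, 1);
  System sys = make_system(pos, sp, box, bonds, z, z, angles, z, kindM, epsM,
                           cutM, shiftM, skin);
  int m = (int)sys.nbr.size();
  IntegerMatrix out(m, 2);
  int q = 0;
  for (int i = 0; i < n; ++i)
    for (int p = sys.nstart[i]; p < sys.nstart[i + 1]; ++p, ++q) {
      out(q, 0) = i + 1; out(q, 1) = sys.nbr[p] + 1;
    }
  return out;
}

// contact histogram by chain separation s = |i - j| for the first n_polymer
// beads (assumed to be in chain order); open boundary, unwrapped coordinates
// [[Rcpp::export(name = ".contact_hist")]]
NumericVector contact_hist_cpp(NumericMatrix pos, int nPolymer, double cutoff) {
  int n = nPolymer;
  std::vector<double> counts(n, 0.0);
  // cell grid over the bounding box
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i) for (int k = 0; k < 3; ++k) {
    lo[k] = std::min(lo[k], pos(i, k)); hi[k] = std::max(hi[k], pos(i, k));
  }
  int nc[3]; double cell[3];
  for (int k = 0; k < 3; ++k) {
    double span = std::max(hi[k] - lo[k], cutoff);
    nc[k] = std::max(1, std::min((int)(span / cutoff), 200));
    cell[k] = span / nc[k] * (1.0 + 1e-12);
  }
  std::vector<int> head(nc[0] * nc[1] * nc[2], -1), nxt(n, -1), ci(3 * n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)((pos(i, k) - lo[k]) / cell[k]);
      if (c[k] >= nc[k]) c[k] = nc[k] - 1;
      ci[3*i+k] = c[k];
    }
    int cc = (c[0] * nc[1] + c[1]) * nc[2] + c[2];
    nxt[i] = head[cc]; head[cc] = i;
  }
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
    for (int dz = -1; dz <= 1; ++dz) {
      int a = ci[3*i] + dx, b = ci[3*i+1] + dy, c = ci[3*i+2] + dz;
      if (a < 0 || a >= nc[0] || b < 0 || b >= nc[1] || c < 0 || c >= nc[2])
        continue;
      for (int j = head[(a * nc[1] + b) * nc[2] + c]; j >= 0; j = nxt[j]) {
        if (j <= i) continue;
        double d0 = pos(i,0) - pos(j,0), d1 = pos(i,1) - pos(j,1),
               d2d = pos(i,2) - pos(j,2);
        if (d0*d0 + d1*d1 + d2d*d2d < c2) counts[std::abs(i - j)] += 1.0;
      }
    }
  }
  return NumericVector(counts.begin(), counts.end());
}
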