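// Bond Fluctuation Model kernel: excluded-volume lattice Monte Carlo with the
// classic 108-vector bond set, Metropolis acceptance for PEG-PEG contact
// energies, and event-driven collision crosslinking between reactive sites.
//
// Conventions shared with the R layer:
//   - coordinates are 0-based integers in [0, L); a monomer at (x,y,z)
//     occupies the 2x2x2 site block {x..x+1}^3 (mod L)
//   - species codes: 0 = PEG, 1 = HEP
//   - all positions passed in/out are R-side 1-free (already 0-based)
#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <map>
#include <functional>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Vec3 { int x, y, z; };

// signed permutations of (2,0,0),(2,1,0),(2,1,1),(2,2,1),(3,0,0),(3,1,0)
static std::vector<Vec3> allowedVectors() {
  std::vector<Vec3> out;
  for (int x = -3; x <= 3; ++x)
    for (int y = -3; y <= 3; ++y)
      for (int z = -3; z <= 3; ++z) {
        int a[3] = { std::abs(x), std::abs(y), std::abs(z) };
        std::sort(a, a + 3);
        bool ok =
          (a[0]==0 && a[1]==0 && a[2]==2) ||
          (a[0]==0 && a[1]==1 && a[2]==2) ||
          (a[0]==1 && a[1]==1 && a[2]==2) ||
          (a[0]==1 && a[1]==2 && a[2]==2) ||
          (a[0]==0 && a[1]==0 && a[2]==3) ||
          (a[0]==0 && a[1]==1 && a[2]==3);
        if (ok) out.push_back({x, y, z});
      }
  return out;
}

// contact shell: minimum-image corner separation with squared length in {4,5,6}
static std::vector<Vec3> shellVectors() {
  std::vector<Vec3> out;
  for (int x = -2; x <= 2; ++x)
    for (int y = -2; y <= 2; ++y)
      for (int z = -2; z <= 2; ++z) {
        int d2 = x*x + y*y + z*z;
        if (d2 >= 4 && d2 <= 6) out.push_back({x, y, z});
      }
  return out;
}

// xoshiro256++ with splitmix64 seeding: fast, seedable, good quality
struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {       // splitmix64 expansion
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline uint32_t below(uint32_t n) {    // Lemire multiply-shift
    return (uint32_t)(((unsigned __int128)next() * n) >> 64);
  }
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

struct Engine {
  int L, n;
  std::vector<int> px, py, pz, spec;
  std::vector<char> reactive, consumed;
  std::vector<int> lat;                       // site -> monomer index + 1
  std::vector<std::vector<int>> nbr;          // bond adjacency
  bool allowedLUT[343];
  std::vector<Vec3> shell;
  double eps;
  Xoshiro rng;
  struct { double operator()(Xoshiro& g) const { return g.u01(); } } U01;

  // hot path: offsets are always within one box length, so conditional
  // subtraction avoids the integer division of a general modulo
  inline int wrap(int a) const {
    if (a >= L) { a -= L; if (a >= L) { a %= L; } }
    else if (a < 0) { a += L; if (a < 0) { a %= L; if (a < 0) a += L; } }
    return a;
  }
  inline size_t sidx(int x, int y, int z) const {
    return (size_t)x + (size_t)L * ((size_t)y + (size_t)L * (size_t)z);
  }
  inline int mi(int d) const {
    if (d >  L / 2) d -= L;
    else if (d < -L / 2) d += L;
    return d;
  }
  inline bool bondOK(int dx, int dy, int dz) const {
    dx = mi(dx); dy = mi(dy); dz = mi(dz);
    if (dx < -3 || dx > 3 || dy < -3 || dy > 3 || dz < -3 || dz > 3)
      return false;
    return allowedLUT[(dx + 3) + 7 * ((dy + 3) + 7 * (dz + 3))];
  }

  void init(int L_, const IntegerMatrix& pos, const IntegerVector& species,
            const IntegerMatrix& bonds, const LogicalVector& reac,
            const LogicalVector& cons, double eps_, uint64_t seed) {
    L = L_; n = pos.nrow(); eps = eps_;
    if (L < 8) stop("box edge must be at least 8 lattice units");
    px.resize(n); py.resize(n); pz.resize(n);
    spec.resize(n); reactive.resize(n); consumed.resize(n);
    for (int i = 0; i < n; ++i) {
      px[i] = wrap(pos(i, 0)); py[i] = wrap(pos(i, 1)); pz[i] = wrap(pos(i, 2));
      spec[i] = species[i];
      reactive[i] = reac[i] ? 1 : 0;
      consumed[i] = cons[i] ? 1 : 0;
    }
    std::fill(allowedLUT, allowedLUT + 343, false);
    for (const Vec3& v : allowedVectors())
      allowedLUT[(v.x + 3) + 7 * ((v.y + 3) + 7 * (v.z + 3))] = true;
    shell = shellVectors();
    lat.assign((size_t)L * L * L, 0);
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            size_t s = sidx(wrap(px[i] + a), wrap(py[i] + b), wrap(pz[i] + c));
            if (lat[s] != 0)
              stop("excluded-volume violation in input state (monomers %d and %d)",
                   lat[s], i + 1);
            lat[s] = i + 1;
          }
    nbr.assign(n, {});
    for (int e = 0; e < bonds.nrow(); ++e) {
      int i = bonds(e, 0), j = bonds(e, 1);
      if (i < 0 || i >= n || j < 0 || j >= n) stop("bond index out of range");
      if (!bondOK(px[i] - px[j], py[i] - py[j], pz[i] - pz[j]))
        stop("bond %d-%d has a disallowed vector in input state", i + 1, j + 1);
      nbr[i].push_back(j);
      nbr[j].push_back(i);
    }
    rng.seed(seed);
  }

  // PEG-PEG contacts of monomer i evaluated as if its corner were at (x,y,z)
  inline int contactsAt(int i, int x, int y, int z) const {
    int c = 0;
    for (const Vec3& v : shell) {
      int sx = wrap(x + v.x), sy = wrap(y + v.y), sz = wrap(z + v.z);
      int o = lat[sidx(sx, sy, sz)];
      if (o > 0) {
        --o;
        if (o != i && spec[o] == 0 &&
            px[o] == sx && py[o] == sy && pz[o] == sz)
          ++c;
      }
    }
    return c;
  }

  // attempt a unit move of monomer i in direction dir (0:+x 1:-x 2:+y 3:-y 4:+z 5:-z)
  bool attempt(int i, int dir) {
    static const int AX[6] = {0, 0, 1, 1, 2, 2};
    static const int SG[6] = {1, -1, 1, -1, 1, -1};
    int axis = AX[dir], sg = SG[dir];
    int x = px[i], y = py[i], z = pz[i];
    // the 4 newly claimed sites (leading face of the moved cube)
    int fx, fy, fz;
    if (axis == 0)      fx = wrap(x + (sg > 0 ? 2 : -1));
    else                fx = 0;
    if (axis == 1)      fy = wrap(y + (sg > 0 ? 2 : -1));
    else                fy = 0;
    if (axis == 2)      fz = wrap(z + (sg > 0 ? 2 : -1));
    else                fz = 0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        int sx, sy, sz;
        if (axis == 0) { sx = fx; sy = wrap(y + a); sz = wrap(z + b); }
        else if (axis == 1) { sx = wrap(x + a); sy = fy; sz = wrap(z + b); }
        else { sx = wrap(x + a); sy = wrap(y + b); sz = fz; }
        if (lat[sidx(sx, sy, sz)] != 0) return false;
      }
    int nx = x, ny = y, nz = z;
    if (axis == 0) nx = wrap(x + sg);
    else if (axis == 1) ny = wrap(y + sg);
    else nz = wrap(z + sg);
    for (int j : nbr[i])
      if (!bondOK(nx - px[j], ny - py[j], nz - pz[j])) return false;
    if (eps != 0.0 && spec[i] == 0) {
      int c0 = contactsAt(i, x, y, z);
      int c1 = contactsAt(i, nx, ny, nz);
      double dE = eps * (c1 - c0);
      if (dE > 0.0 && U01(rng) >= std::exp(-dE)) return false;
    }
    // commit: only the trailing face is vacated and the leading face claimed
    int tx = 0, ty = 0, tz = 0;   // trailing-face fixed coordinate
    if (axis == 0)      tx = wrap(x + (sg > 0 ? 0 : 1));
    else if (axis == 1) ty = wrap(y + (sg > 0 ? 0 : 1));
    else                tz = wrap(z + (sg > 0 ? 0 : 1));
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        int cx, cy, cz, sx2, sy2, sz2;
        if (axis == 0) {
          cx = tx; cy = wrap(y + a); cz = wrap(z + b);
          sx2 = fx; sy2 = cy; sz2 = cz;
        } else if (axis == 1) {
          cx = wrap(x + a); cy = ty; cz = wrap(z + b);
          sx2 = cx; sy2 = fy; sz2 = cz;
        } else {
          cx = wrap(x + a); cy = wrap(y + b); cz = tz;
          sx2 = cx; sy2 = cy; sz2 = fz;
        }
        lat[sidx(cx, cy, cz)] = 0;
        lat[sidx(sx2, sy2, sz2)] = i + 1;
      }
    px[i] = nx; py[i] = ny; pz[i] = nz;
    return true;
  }

  // after an accepted move of a reactive unconsumed monomer: look for unconsumed
  // partner sites of the other species one allowed bond vector away
  int collisionPartner(int i, const std::vector<Vec3>& bvec,
                       std::vector<int>& cand) {
    cand.clear();
    for (const Vec3& v : bvec) {
      int sx = wrap(px[i] + v.x), sy = wrap(py[i] + v.y), sz = wrap(pz[i] + v.z);
      int o = lat[sidx(sx, sy, sz)];
      if (o > 0) {
        --o;
        if (spec[o] != spec[i] && reactive[o] && !consumed[o] &&
            px[o] == sx && py[o] == sy && pz[o] == sz)
          cand.push_back(o);
      }
    }
    if (cand.empty()) return -1;
    if (cand.size() == 1) return cand[0];
    return cand[rng.below((uint32_t)cand.size())];
  }
};

} // namespace

//' @keywords internal
// [[Rcpp::export(name = ".bfm_run_cpp")]]
List bfm_run_cpp(int L, IntegerMatrix pos, IntegerVector species,
                 IntegerMatrix bonds, LogicalVector reactive,
                 LogicalVector consumed, double nMCS, double epsPP,
                 bool crosslinkOn, int targetNewBonds, double seed) {
  Engine E;
  E.init(L, pos, species, bonds, reactive, consumed, epsPP,
         (uint64_t)(int64_t)seed);
  const std::vector<Vec3> bvec = allowedVectors();
  std::vector<int> cand;
  const int n = E.n;
  long long total = (long long)std::llround(nMCS * n);
  long long accepted = 0, done = 0;
  std::vector<int> newI, newJ;
  std::vector<double> newT;
  bool reached = !crosslinkOn || targetNewBonds <= 0;
  for (long long t = 0; t < total; ++t) {
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    int i = (int)E.rng.below((uint32_t)n);
    int dir = (int)E.rng.below(6u);
    bool acc = E.attempt(i, dir);
    ++done;
    if (acc) {
      ++accepted;
      if (crosslinkOn && E.reactive[i] && !E.consumed[i]) {
        int j = E.collisionPartner(i, bvec, cand);
        if (j >= 0) {
          E.consumed[i] = 1; E.consumed[j] = 1;
          E.nbr[i].push_back(j); E.nbr[j].push_back(i);
          int peg = (E.spec[i] == 0) ? i : j;
          int hep = (E.spec[i] == 0) ? j : i;
          newI.push_back(peg + 1);
          newJ.push_back(hep + 1);
          newT.push_back((double)done / n);
          if ((int)newI.size() >= targetNewBonds) { reached = true; break; }
        }
      }
    }
  }
  IntegerMatrix outPos(n, 3);
  LogicalVector outCons(n);
  for (int i = 0; i < n; ++i) {
    outPos(i, 0) = E.px[i]; outPos(i, 1) = E.py[i]; outPos(i, 2) = E.pz[i];
    outCons[i] = E.consumed[i] != 0;
  }
  IntegerMatrix nb(newI.size(), 2);
  for (size_t k = 0; k < newI.size(); ++k) {
    nb(k, 0) = newI[k]; nb(k, 1) = newJ[k];
  }
  return List::create(_["pos"] = outPos, _["consumed"] = outCons,
                      _["newBonds"] = nb, _["eventMCS"] = wrap(newT),
                      _["attempts"] = (double)done,
                      _["accepted"] = (double)accepted,
                      _["mcsDone"] = (double)done / n,
                      _["reachedTarget"] = reached);
}

//' @keywords internal
// [[Rcpp::export(name = ".bfm_attempt_move_cpp")]]
List bfm_attempt_move_cpp(int L, IntegerMatrix pos, IntegerVector species,
                          IntegerMatrix bonds, double epsPP, int monomer,
                          int dir, double seed) {
  Engine E;
  LogicalVector reac(pos.nrow()), cons(pos.nrow());
  E.init(L, pos, species, bonds, reac, cons, epsPP, (uint64_t)(int64_t)seed);
  if (monomer < 0 || monomer >= E.n) stop("invalid monomer index");
  if (dir < 0 || dir > 5) stop("invalid direction");
  bool acc = E.attempt(monomer, dir);
  IntegerMatrix outPos(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    outPos(i, 0) = E.px[i]; outPos(i, 1) = E.py[i]; outPos(i, 2) = E.pz[i];
  }
  return List::create(_["accepted"] = acc, _["pos"] = outPos);
}

//' @keywords internal
// [[Rcpp::export(name = ".contact_energy_cpp")]]
double contact_energy_cpp(int L, IntegerMatrix pos, IntegerVector species,
                          double epsPP) {
  Engine E;
  LogicalVector reac(pos.nrow()), cons(pos.nrow());
  IntegerMatrix noBonds(0, 2);
  E.init(L, pos, species, noBonds, reac, cons, epsPP, 1u);
  long long pairs = 0;
  for (int i = 0; i < E.n; ++i)
    if (E.spec[i] == 0)
      pairs += E.contactsAt(i, E.px[i], E.py[i], E.pz[i]);
  return epsPP * (double)(pairs / 2);
}

//' @keywords internal
// [[Rcpp::export(name = ".audit_cpp")]]
List audit_cpp(int L, IntegerMatrix pos, IntegerMatrix bonds) {
  // standalone invariant audit: excluded volume + allowed bond vectors
  int n = pos.nrow();
  Engine E;
  E.L = L;
  std::fill(E.allowedLUT, E.allowedLUT + 343, false);
  for (const Vec3& v : allowedVectors())
    E.allowedLUT[(v.x + 3) + 7 * ((v.y + 3) + 7 * (v.z + 3))] = true;
  std::vector<int> lat((size_t)L * L * L, 0);
  int overlaps = 0;
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          size_t s = E.sidx(E.wrap(pos(i,0) + a), E.wrap(pos(i,1) + b),
                            E.wrap(pos(i,2) + c));
          if (lat[s] != 0) ++overlaps;
          lat[s] = i + 1;
        }
  int badBonds = 0;
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0), j = bonds(e, 1);
    if (!E.bondOK(pos(i,0) - pos(j,0), pos(i,1) - pos(j,1),
                  pos(i,2) - pos(j,2)))
      ++badBonds;
  }
  return List::create(_["overlaps"] = overlaps, _["badBonds"] = badBonds);
}

//' @keywords internal
// [[Rcpp::export(name = ".unwrap_cpp")]]
List unwrap_cpp(int L, IntegerMatrix pos, IntegerMatrix bonds) {
  // unwrap coordinates across periodic boundaries by BFS over the bond graph;
  // back-edges whose minimum-image displacement disagrees with the unwrapped
  // one mark a component as winding the box
  int n = pos.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < bonds.nrow(); ++e) {
    adj[bonds(e, 0)].push_back(bonds(e, 1));
    adj[bonds(e, 1)].push_back(bonds(e, 0));
  }
  auto mi = [&](int d) {
    if (d > L / 2) d -= L; else if (d < -L / 2) d += L; return d;
  };
  NumericMatrix out(n, 3);
  IntegerVector comp(n, -1);
  std::vector<char> compConsistent;
  std::vector<int> queue;
  int nc = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    bool consistent = true;
    comp[s] = nc;
    out(s, 0) = pos(s, 0); out(s, 1) = pos(s, 1); out(s, 2) = pos(s, 2);
    queue.clear(); queue.push_back(s);
    size_t h = 0;
    while (h < queue.size()) {
      int u = queue[h++];
      for (int v : adj[u]) {
        int dx = mi(pos(v,0) - pos(u,0));
        int dy = mi(pos(v,1) - pos(u,1));
        int dz = mi(pos(v,2) - pos(u,2));
        if (comp[v] < 0) {
          comp[v] = nc;
          out(v, 0) = out(u, 0) + dx;
          out(v, 1) = out(u, 1) + dy;
          out(v, 2) = out(u, 2) + dz;
          queue.push_back(v);
        } else {
          if (std::lround(out(v,0) - out(u,0)) != dx ||
              std::lround(out(v,1) - out(u,1)) != dy ||
              std::lround(out(v,2) - out(u,2)) != dz)
            consistent = false;
        }
      }
    }
    compConsistent.push_back(consistent ? 1 : 0);
    ++nc;
  }
  LogicalVector cons(nc);
  for (int k = 0; k < nc; ++k) cons[k] = compConsistent[k] != 0;
  return List::create(_["coords"] = out, _["component"] = comp,
                      _["consistent"] = cons);
}

//' @keywords internal
// [[Rcpp::export(name = ".void_probe_cpp")]]
NumericVector void_probe_cpp(int L, IntegerMatrix pos, int nProbes,
                             double seed) {
  // largest-empty-sphere sampling: radius from a random probe point to the
  // nearest occupied site of any monomer cube, with periodic minimum image
  int n = pos.nrow();
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  std::uniform_real_distribution<double> U(0.0, (double)L);
  NumericVector out(nProbes);
  double cap = L / 2.0;
  for (int p = 0; p < nProbes; ++p) {
    double x = U(rng), y = U(rng), z = U(rng);
    double best = cap;
    for (int i = 0; i < n; ++i) {
      // cube center is corner + 1 in continuous site coordinates (span 2)
      double dx = x - (pos(i,0) + 1.0);
      double dy = y - (pos(i,1) + 1.0);
      double dz = z - (pos(i,2) + 1.0);
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      dx = std::max(0.0, std::fabs(dx) - 1.0);
      dy = std::max(0.0, std::fabs(dy) - 1.0);
      dz = std::max(0.0, std::fabs(dz) - 1.0);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    out[p] = best;
  }
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".peg_clusters_cpp")]]
IntegerVector peg_clusters_cpp(int L, IntegerMatrix pos,
                               IntegerVector species) {
  // connected components of PEG monomers under contact-shell adjacency
  int n = pos.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  Engine E;
  E.L = L;
  auto wrapi = [&](int a) { a %= L; return a < 0 ? a + L : a; };
  std::vector<int> corner((size_t)L * L * L, 0);
  for (int i = 0; i < n; ++i)
    if (species[i] == 0)
      corner[E.sidx(wrapi(pos(i,0)), wrapi(pos(i,1)), wrapi(pos(i,2)))] = i + 1;
  for (const Vec3& v : shellVectors())
    for (int i = 0; i < n; ++i) {
      if (species[i] != 0) continue;
      int o = corner[E.sidx(wrapi(pos(i,0) + v.x), wrapi(pos(i,1) + v.y),
                            wrapi(pos(i,2) + v.z))];
      if (o > 0) {
        int ra = find(i), rb = find(o - 1);
        if (ra != rb) parent[ra] = rb;
      }
    }
  IntegerVector lab(n, 0);
  std::map<int, int> relabel;
  for (int i = 0; i < n; ++i)
    if (species[i] == 0) {
      int r = find(i);
      auto it = relabel.find(r);
      if (it == relabel.end()) {
        int id = (int)relabel.size() + 1;
        relabel[r] = id;
        lab[i] = id;
      } else lab[i] = it->second;
    }
  return lab;
}

//' @keywords internal
// [[Rcpp::export(name = ".skeletonize_cpp")]]
IntegerMatrix skeletonize_cpp(IntegerMatrix img) {
  // Zhang-Suen thinning of a binary image down to a 1-px skeleton
  int nr = img.nrow(), nc = img.ncol();
  std::vector<char> A((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      A[(size_t)i + (size_t)nr * j] = img(i, j) != 0;
  auto at = [&](int i, int j) -> char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return A[(size_t)i + (size_t)nr * j];
  };
  std::vector<std::pair<int,int>> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!at(i, j)) continue;
          // neighbours P2..P9 clockwise starting north
          int p[8] = { at(i-1,j), at(i-1,j+1), at(i,j+1), at(i+1,j+1),
                       at(i+1,j), at(i+1,j-1), at(i,j-1), at(i-1,j-1) };
          int B = p[0]+p[1]+p[2]+p[3]+p[4]+p[5]+p[6]+p[7];
          if (B < 2 || B > 6) continue;
          int Ac = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++Ac;
          if (Ac != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back({i, j});
        }
      for (auto& k : kill) A[(size_t)k.first + (size_t)nr * k.second] = 0;
      if (!kill.empty()) changed = true;
    }
  }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = A[(size_t)i + (size_t)nr * j];
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".debye_cpp")]]
NumericVector debye_cpp(NumericMatrix pts, NumericVector w, NumericVector q) {
  // orientation-averaged Debye sum I(q) = sum_ij wi wj sin(q rij)/(q rij)
  int n = pts.nrow(), nq = q.size();
  NumericVector out(nq);
  double diag = 0.0;
  for (int i = 0; i < n; ++i) diag += w[i] * w[i];
  std::vector<double> rij;
  std::vector<double> wij;
  rij.reserve((size_t)n * (n - 1) / 2);
  wij.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i,0) - pts(j,0);
      double dy = pts(i,1) - pts(j,1);
      double dz = pts(i,2) - pts(j,2);
      rij.push_back(std::sqrt(dx*dx + dy*dy + dz*dz));
      wij.push_back(w[i] * w[j]);
    }
  for (int k = 0; k < nq; ++k) {
    double qq = q[k], s = diag;
    for (size_t m = 0; m < rij.size(); ++m) {
      double x = qq * rij[m];
      s += 2.0 * wij[m] * (x < 1e-8 ? 1.0 : std::sin(x) / x);
    }
    out[k] = s;
  }
  return out;
}
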