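// Rigid-body Langevin dynamics engine.
//
// Bodies are identical rigid assemblies of pseudoatoms (one template per
// run).  Pairwise pseudoatom interactions (WCA / Morse / cut-shifted LJ)
// act under the minimum-image convention; the implicit condensate couples
// to each body center.  Translation uses a BAOAB Langevin splitting;
// rotation uses body-frame angular momenta with a symplectic free-rotor
// (axis-permutation) update and an Ornstein-Uhlenbeck kick per principal
// axis.  gamma = 0 recovers NVE velocity Verlet.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <chrono>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

// phase timing diagnostics (enabled via engine_profile_cpp)
static bool g_profile = false;
static double g_t_pairs = 0, g_t_build = 0, g_t_atoms = 0, g_t_reduce = 0,
              g_t_drift = 0, g_t_noise = 0, g_t_kick = 0, g_t_check = 0;
struct PhaseTimer {
  std::chrono::high_resolution_clock::time_point t0;
  double* acc;
  explicit PhaseTimer(double* a) : acc(a) {
    if (g_profile) t0 = std::chrono::high_resolution_clock::now();
  }
  ~PhaseTimer() {
    if (g_profile) {
      auto t1 = std::chrono::high_resolution_clock::now();
      *acc += std::chrono::duration<double>(t1 - t0).count();
    }
  }
};

// [[Rcpp::export]]
Rcpp::List engine_profile_cpp(bool enable) {
  using namespace Rcpp;
  List out = List::create(
    _["pairs"] = g_t_pairs, _["build"] = g_t_build, _["atoms"] = g_t_atoms,
    _["reduce"] = g_t_reduce, _["drift"] = g_t_drift,
    _["noise"] = g_t_noise, _["kick"] = g_t_kick, _["check"] = g_t_check);
  g_profile = enable;
  g_t_pairs = g_t_build = g_t_atoms = g_t_reduce = 0;
  g_t_drift = g_t_noise = g_t_kick = g_t_check = 0;
  return out;
}

using namespace Rcpp;

// ---------------------------------------------------------------------
// deterministic RNG (xoshiro256++ seeded via splitmix64)

struct Xoshiro {
  uint64_t s[4];
  bool have_cached;
  double cached;
  explicit Xoshiro(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() {   // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {    // Box-Muller with caching
    if (have_cached) { have_cached = false; return cached; }
    double r = std::sqrt(-2.0 * std::log(uniform()));
    double a = 6.283185307179586476925286766559 * uniform();
    cached = r * std::sin(a); have_cached = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------
// quaternion helpers (w, x, y, z); R(q) maps body -> world

static inline void quat_to_mat(const double* q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// sin/cos accurate to double precision for the small per-substep rotation
// angles of the free-rotor update (|a| << 1), falling back to libm
static inline void fast_sincos(double a, double& s, double& c) {
  double a2 = a * a;
  if (a2 < 1e-4) {
    s = a * (1.0 - a2 / 6.0 * (1.0 - a2 / 20.0 * (1.0 - a2 / 42.0)));
    c = 1.0 - a2 / 2.0 * (1.0 - a2 / 12.0 * (1.0 - a2 / 30.0));
  } else {
    s = std::sin(a); c = std::cos(a);
  }
}

static inline void quat_mul_axis_sc(double* q, int axis, double s, double c) {
  // q <- q (x) dq, dq given by the half-angle sine and cosine
  double w = q[0], x = q[1], y = q[2], z = q[3];
  if (axis == 0) {        // x
    q[0] = w * c - x * s; q[1] = w * s + x * c;
    q[2] = y * c + z * s; q[3] = z * c - y * s;
  } else if (axis == 1) { // y
    q[0] = w * c - y * s; q[1] = x * c - z * s;
    q[2] = w * s + y * c; q[3] = z * c + x * s;
  } else {                // z
    q[0] = w * c - z * s; q[1] = x * c + y * s;
    q[2] = y * c - x * s; q[3] = w * s + z * c;
  }
}

static inline void renorm_quat(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

// rotate body angular momentum components when the body rotates by `ang`
// about principal axis `axis`
static inline void rotate_L_sc(double* L, int axis, double s, double c) {
  int a = (axis + 1) % 3, b = (axis + 2) % 3;
  double La = c * L[a] + s * L[b];
  double Lb = -s * L[a] + c * L[b];
  L[a] = La; L[b] = Lb;
}

// ---------------------------------------------------------------------
// system container

struct Engine {
  int N;                // bodies
  int n_at;             // atoms per body
  int M;                // total atoms
  double L, halfL;
  double mass;
  double I[3], invI[3];
  // template
  std::vector<double> off;      // n_at x 3 body-frame offsets
  std::vector<int> type;        // n_at, 0-based
  int ntypes;
  // rules (ntypes x ntypes, row-major)
  std::vector<int> kind;        // 0 none, 1 WCA, 2 MORSE, 3 LJ
  std::vector<double> p_eps, p_par, p_rcut2, p_shift;
  double max_rcut;
  // condensate
  double epsc, Rc, alphaC;
  // state
  std::vector<double> x, v, q, Lb;  // N x 3 / N x 4
  std::vector<int> image;           // N x 3
  // scratch
  std::vector<double> atw;          // M x 3 world atom positions
  std::vector<double> fat;          // M x 3 atom forces
  std::vector<double> F, Tau;       // N x 3 body force / world torque
  std::vector<double> Rmat;         // N x 9 cached rotation matrices
  // neighbor list
  double skin, rlist, rlist2;
  double body_rmax;                 // largest pseudoatom offset
  std::vector<int> pairs_i, pairs_j;
  std::vector<int> cell_head, cell_next;
  std::vector<double> xref_b;       // N x 3 body centers at last build
  std::vector<double> qref_b;       // N x 4 orientations at last build
  std::vector<char> in_list;        // atom appears in the pair list
  bool list_valid;

  double epot;

  void wrap(int i) {
    for (int k = 0; k < 3; ++k) {
      double& c = x[3 * i + k];
      while (c >= halfL) { c -= L; image[3 * i + k]++; }
      while (c < -halfL) { c += L; image[3 * i + k]--; }
    }
  }

  inline double min_img(double d) const {
    if (d >= halfL) d -= L;
    else if (d < -halfL) d += L;
    return d;
  }

  void update_rotations() {
    for (int i = 0; i < N; ++i) quat_to_mat(&q[4 * i], &Rmat[9 * i]);
  }

  // world positions from the cached rotation matrices; when `all` is false
  // only atoms referenced by the current pair list are updated
  void compute_atoms(bool all) {
    for (int i = 0; i < N; ++i) {
      const double* R = &Rmat[9 * i];
      for (int a = 0; a < n_at; ++a) {
        int ia = i * n_at + a;
        if (!all && !in_list[ia]) continue;
        const double* o = &off[3 * a];
        double* w = &atw[3 * ia];
        for (int k = 0; k < 3; ++k) {
          w[k] = x[3 * i + k] + R[3 * k] * o[0] + R[3 * k + 1] * o[1] +
                 R[3 * k + 2] * o[2];
        }
      }
    }
  }

  void build_list() {
    pairs_i.clear(); pairs_j.clear();
    int nc = (int)std::floor(L / rlist);
    // keep the total cell count commensurate with the atom count so the
    // per-rebuild grid reset stays cheap
    int nc_cap = (int)std::cbrt(32.0 * M) + 1;
    if (nc > nc_cap) nc = nc_cap;
    if (nc < 3) {
      // all-pairs build
      for (int a = 0; a < M; ++a) {
        for (int b = a + 1; b < M; ++b) {
          if (a / n_at == b / n_at) continue;
          double dx = min_img(atw[3 * a] - atw[3 * b]);
          double dy = min_img(atw[3 * a + 1] - atw[3 * b + 1]);
          double dz = min_img(atw[3 * a + 2] - atw[3 * b + 2]);
          if (dx * dx + dy * dy + dz * dz < rlist2) {
            pairs_i.push_back(a); pairs_j.push_back(b);
          }
        }
      }
    } else {
      double cw = L / nc;
      int ncc = nc * nc * nc;
      if ((int)cell_head.size() != ncc) cell_head.assign(ncc, -1);
      else std::fill(cell_head.begin(), cell_head.end(), -1);
      if ((int)cell_next.size() != M) cell_next.assign(M, -1);
      std::vector<int>& head = cell_head;
      std::vector<int>& nxt = cell_next;
      std::vector<int> cx(M), cy(M), cz(M);
      for (int a = 0; a < M; ++a) {
        int ix = (int)std::floor((atw[3 * a] + halfL) / cw);
        int iy = (int)std::floor((atw[3 * a + 1] + halfL) / cw);
        int iz = (int)std::floor((atw[3 * a + 2] + halfL) / cw);
        ix = ((ix % nc) + nc) % nc; iy = ((iy % nc) + nc) % nc;
        iz = ((iz % nc) + nc) % nc;
        cx[a] = ix; cy[a] = iy; cz[a] = iz;
        int c = (ix * nc + iy) * nc + iz;
        nxt[a] = head[c]; head[c] = a;
      }
      // loop over atoms, scanning the 27 neighbor cells; keep b > a so
      // each unordered pair is stored once
      for (int a = 0; a < M; ++a) {
        for (int ddx = -1; ddx <= 1; ++ddx) {
          int jx = cx[a] + ddx; if (jx < 0) jx += nc; else if (jx >= nc) jx -= nc;
          for (int ddy = -1; ddy <= 1; ++ddy) {
            int jy = cy[a] + ddy; if (jy < 0) jy += nc; else if (jy >= nc) jy -= nc;
            for (int ddz = -1; ddz <= 1; ++ddz) {
              int jz = cz[a] + ddz; if (jz < 0) jz += nc; else if (jz >= nc) jz -= nc;
              int c2 = (jx * nc + jy) * nc + jz;
              for (int b = head[c2]; b >= 0; b = nxt[b]) {
                if (b <= a) continue;
                if (a / n_at == b / n_at) continue;
                double dx = min_img(atw[3 * a] - atw[3 * b]);
                double dy = min_img(atw[3 * a + 1] - atw[3 * b + 1]);
                double dz = min_img(atw[3 * a + 2] - atw[3 * b + 2]);
                if (dx * dx + dy * dy + dz * dz < rlist2) {
                  pairs_i.push_back(a); pairs_j.push_back(b);
                }
              }
            }
          }
        }
      }
    }
    std::copy(x.begin(), x.end(), xref_b.begin());
    std::copy(q.begin(), q.end(), qref_b.begin());
    std::fill(in_list.begin(), in_list.end(), 0);
    for (size_t p = 0; p < pairs_i.size(); ++p) {
      in_list[pairs_i[p]] = 1; in_list[pairs_j[p]] = 1;
    }
    list_valid = true;
  }

  // any pseudoatom may have moved by at most the center displacement plus
  // the rotation angle times the body radius
  bool need_rebuild() const {
    if (!list_valid) return true;
    double lim = 0.5 * skin;
    for (int i = 0; i < N; ++i) {
      double dx = min_img(x[3 * i] - xref_b[3 * i]);
      double dy = min_img(x[3 * i + 1] - xref_b[3 * i + 1]);
      double dz = min_img(x[3 * i + 2] - xref_b[3 * i + 2]);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dot = std::fabs(q[4 * i] * qref_b[4 * i] +
                             q[4 * i + 1] * qref_b[4 * i + 1] +
                             q[4 * i + 2] * qref_b[4 * i + 2] +
                             q[4 * i + 3] * qref_b[4 * i + 3]);
      // theta = 2 acos(dot) <= 2.23 sqrt(2 (1 - dot)) for dot in [0, 1]
      double theta = 2.23 * std::sqrt(2.0 * std::max(0.0, 1.0 - dot));
      if (d + theta * body_rmax > lim) return true;
    }
    return false;
  }

  void forces() {
    {
      PhaseTimer pt(&g_t_check);
      update_rotations();
    }
    bool rb;
    {
      PhaseTimer pt(&g_t_check);
      rb = need_rebuild();
    }
    if (rb) {
      PhaseTimer pt(&g_t_build);
      compute_atoms(true);
      build_list();
    } else {
      PhaseTimer pt(&g_t_atoms);
      compute_atoms(false);
    }
    std::fill(fat.begin(), fat.end(), 0.0);
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(Tau.begin(), Tau.end(), 0.0);
    epot = 0.0;
    PhaseTimer pt_pairs(&g_t_pairs);
    size_t np = pairs_i.size();
    for (size_t p = 0; p < np; ++p) {
      int a = pairs_i[p], b = pairs_j[p];
      int ta = type[a % n_at], tb = type[b % n_at];
      int kd = kind[ta * ntypes + tb];
      if (kd == 0) continue;
      double dx = min_img(atw[3 * a] - atw[3 * b]);
      double dy = min_img(atw[3 * a + 1] - atw[3 * b + 1]);
      double dz = min_img(atw[3 * a + 2] - atw[3 * b + 2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      int idx = ta * ntypes + tb;
      if (r2 >= p_rcut2[idx]) continue;
      double e = p_eps[idx], fOverR = 0.0, en = 0.0;
      if (kd == 1 || kd == 3) {           // WCA / LJ
        double sg = p_par[idx];
        if (r2 < 2.5e-3 * sg * sg) {
          stop("pseudoatom overlap below numerical floor (bodies %d, %d)",
               a / n_at + 1, b / n_at + 1);
        }
        double sr2 = sg * sg / r2;
        double sr6 = sr2 * sr2 * sr2;
        en = 4.0 * e * (sr6 * sr6 - sr6) - p_shift[idx];
        if (kd == 1) en += e;
        fOverR = 24.0 * e * (2.0 * sr6 * sr6 - sr6) / r2;
      } else {                            // MORSE, r_eq = 0
        double al = p_par[idx];
        if (r2 < 1e-18) {
          en = -e - p_shift[idx];         // coincident attractors: min, F=0
        } else {
          double r = std::sqrt(r2);
          double ex = std::exp(-al * r);
          en = e * (ex * ex - 2.0 * ex) - p_shift[idx];
          double dEdr = 2.0 * al * e * ex * (1.0 - ex);
          fOverR = -dEdr / r;
        }
      }
      epot += en;
      fat[3 * a] += fOverR * dx; fat[3 * a + 1] += fOverR * dy;
      fat[3 * a + 2] += fOverR * dz;
      fat[3 * b] -= fOverR * dx; fat[3 * b + 1] -= fOverR * dy;
      fat[3 * b + 2] -= fOverR * dz;
    }
    // reduce atom forces to body force and torque
    PhaseTimer pt_reduce(&g_t_reduce);
    for (int i = 0; i < N; ++i) {
      for (int a = 0; a < n_at; ++a) {
        int ia = i * n_at + a;
        double fx = fat[3 * ia], fy = fat[3 * ia + 1], fz = fat[3 * ia + 2];
        if (fx == 0.0 && fy == 0.0 && fz == 0.0) continue;
        double dx = atw[3 * ia] - x[3 * i];
        double dy = atw[3 * ia + 1] - x[3 * i + 1];
        double dz = atw[3 * ia + 2] - x[3 * i + 2];
        F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
        Tau[3 * i] += dy * fz - dz * fy;
        Tau[3 * i + 1] += dz * fx - dx * fz;
        Tau[3 * i + 2] += dx * fy - dy * fx;
      }
      // condensate field at the body center
      if (epsc > 0.0) {
        double rx = x[3 * i], ry = x[3 * i + 1], rz = x[3 * i + 2];
        double r = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (r < Rc) {
          epot += -epsc;
        } else {
          double ex = std::exp(-alphaC * (r - Rc));
          epot += -epsc * (2.0 * ex - ex * ex);
          if (r > 0) {
            double dudr = 2.0 * alphaC * epsc * ex * (1.0 - ex);
            double fr = -dudr / r;
            F[3 * i] += fr * rx; F[3 * i + 1] += fr * ry;
            F[3 * i + 2] += fr * rz;
          }
        }
      }
    }
  }

  void free_rotor(int i, double h) {
    double* qq = &q[4 * i];
    double* LL = &Lb[3 * i];
    // sequence: z/2, y/2, x, y/2, z/2
    static const int order[5] = {2, 1, 0, 1, 2};
    static const double frac[5] = {0.5, 0.5, 1.0, 0.5, 0.5};
    for (int s = 0; s < 5; ++s) {
      int ax = order[s];
      double ang = h * frac[s] * LL[ax] * invI[ax];
      double sh, ch;
      fast_sincos(0.5 * ang, sh, ch);
      quat_mul_axis_sc(qq, ax, sh, ch);
      // full-angle sine/cosine from the half angle
      rotate_L_sc(LL, ax, 2.0 * sh * ch, ch * ch - sh * sh);
    }
  }
};

static void parse_rules(List rules, Engine& E) {
  IntegerMatrix kindM = rules["kind"];
  NumericMatrix epsM = rules["eps"], parM = rules["par"],
                rcutM = rules["rcut"], shiftM = rules["shift"];
  int nt = kindM.nrow();
  E.ntypes = nt;
  E.kind.assign(nt * nt, 0);
  E.p_eps.assign(nt * nt, 0.0); E.p_par.assign(nt * nt, 0.0);
  E.p_rcut2.assign(nt * nt, 0.0); E.p_shift.assign(nt * nt, 0.0);
  E.max_rcut = 0.0;
  for (int i = 0; i < nt; ++i) for (int j = 0; j < nt; ++j) {
    E.kind[i * nt + j] = kindM(i, j);
    E.p_eps[i * nt + j] = epsM(i, j);
    E.p_par[i * nt + j] = parM(i, j);
    E.p_rcut2[i * nt + j] = rcutM(i, j) * rcutM(i, j);
    E.p_shift[i * nt + j] = shiftM(i, j);
    if (kindM(i, j) != 0 && rcutM(i, j) > E.max_rcut)
      E.max_rcut = rcutM(i, j);
  }
}

static void init_engine(Engine& E, NumericMatrix centers, NumericMatrix quats,
                        NumericMatrix vels, NumericMatrix angmom,
                        IntegerMatrix images, double boxL,
                        NumericMatrix atom_pos, IntegerVector atom_type,
                        List rules, NumericVector inertia, double mass,
                        double epsc, double Rc, double alphaC, double skin) {
  E.N = centers.nrow();
  E.n_at = atom_pos.nrow();
  E.M = E.N * E.n_at;
  E.L = boxL; E.halfL = 0.5 * boxL;
  E.mass = mass;
  for (int k = 0; k < 3; ++k) { E.I[k] = inertia[k]; E.invI[k] = 1.0 / inertia[k]; }
  E.off.resize(3 * E.n_at);
  E.type.resize(E.n_at);
  for (int a = 0; a < E.n_at; ++a) {
    for (int k = 0; k < 3; ++k) E.off[3 * a + k] = atom_pos(a, k);
    E.type[a] = atom_type[a];
  }
  parse_rules(rules, E);
  E.epsc = epsc; E.Rc = Rc; E.alphaC = alphaC;
  E.x.resize(3 * E.N); E.v.resize(3 * E.N);
  E.q.resize(4 * E.N); E.Lb.resize(3 * E.N);
  E.image.resize(3 * E.N);
  for (int i = 0; i < E.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      E.x[3 * i + k] = centers(i, k);
      E.v[3 * i + k] = vels(i, k);
      E.Lb[3 * i + k] = angmom(i, k);
      E.image[3 * i + k] = images(i, k);
    }
    for (int k = 0; k < 4; ++k) E.q[4 * i + k] = quats(i, k);
    E.wrap(i);
  }
  E.atw.resize(3 * E.M); E.fat.resize(3 * E.M);
  E.F.resize(3 * E.N); E.Tau.resize(3 * E.N);
  E.Rmat.resize(9 * E.N);
  E.xref_b.resize(3 * E.N); E.qref_b.resize(4 * E.N);
  E.in_list.assign(E.M, 0);
  E.body_rmax = 0.0;
  for (int a = 0; a < E.n_at; ++a) {
    double r2 = E.off[3 * a] * E.off[3 * a] +
                E.off[3 * a + 1] * E.off[3 * a + 1] +
                E.off[3 * a + 2] * E.off[3 * a + 2];
    if (r2 > E.body_rmax * E.body_rmax) E.body_rmax = std::sqrt(r2);
  }
  E.skin = skin;
  E.rlist = E.max_rcut + skin;
  E.rlist2 = E.rlist * E.rlist;
  E.list_valid = false;
}

// [[Rcpp::export]]
List engine_forces_cpp(NumericMatrix centers, NumericMatrix quats,
                       double boxL, NumericMatrix atom_pos,
                       IntegerVector atom_type, List rules,
                       NumericVector inertia, double mass, double epsc,
                       double Rc, double alphaC, double skin) {
  Engine E;
  NumericMatrix zeros(centers.nrow(), 3);
  IntegerMatrix izeros(centers.nrow(), 3);
  init_engine(E, centers, quats, zeros, zeros, izeros, boxL, atom_pos,
              atom_type, rules, inertia, mass, epsc, Rc, alphaC, skin);
  E.forces();
  NumericMatrix Fout(E.N, 3), Tout(E.N, 3), Tbody(E.N, 3);
  double R[9];
  for (int i = 0; i < E.N; ++i) {
    quat_to_mat(&E.q[4 * i], R);
    for (int k = 0; k < 3; ++k) {
      Fout(i, k) = E.F[3 * i + k];
      Tout(i, k) = E.Tau[3 * i + k];
    }
    for (int k = 0; k < 3; ++k) {  // body torque = R^T tau_world
      Tbody(i, k) = R[3 * 0 + k] * E.Tau[3 * i] +
                    R[3 * 1 + k] * E.Tau[3 * i + 1] +
                    R[3 * 2 + k] * E.Tau[3 * i + 2];
    }
  }
  return List::create(_["forces"] = Fout, _["torques"] = Tout,
                      _["torques_body"] = Tbody, _["energy"] = E.epot);
}

// [[Rcpp::export]]
List engine_run_cpp(NumericMatrix centers, NumericMatrix quats,
                    NumericMatrix vels, NumericMatrix angmom,
                    IntegerMatrix images, double boxL,
                    NumericMatrix atom_pos, IntegerVector atom_type,
                    List rules, NumericVector inertia, double mass,
                    double epsc, double Rc, double alphaC, double dt,
                    double gamma, NumericVector gamma_rot, double Tset,
                    int n_steps, int snap_stride, double seed, double t0,
                    double skin) {
  Engine E;
  init_engine(E, centers, quats, vels, angmom, images, boxL, atom_pos,
              atom_type, rules, inertia, mass, epsc, Rc, alphaC, skin);
  Xoshiro rng((uint64_t)seed);

  // friction/noise coefficients
  double c1t = (gamma > 0) ? std::exp(-gamma * dt / E.mass) : 1.0;
  double c2t = (gamma > 0) ? std::sqrt((1.0 - c1t * c1t) * Tset / E.mass) : 0.0;
  double c1r[3], c2r[3];
  for (int k = 0; k < 3; ++k) {
    if (gamma_rot[k] > 0) {
      c1r[k] = std::exp(-gamma_rot[k] * dt / E.I[k]);
      c2r[k] = std::sqrt((1.0 - c1r[k] * c1r[k]) * Tset * E.I[k]);
    } else { c1r[k] = 1.0; c2r[k] = 0.0; }
  }

  int n_snap = n_steps / snap_stride + 1;
  if (n_steps % snap_stride != 0) n_snap += 1;
  NumericVector snap_t(n_snap), snap_epot(n_snap), snap_ekin(n_snap);
  NumericVector sx(n_snap * E.N * 3), sq(n_snap * E.N * 4);
  IntegerVector sim(n_snap * E.N * 3);

  E.forces();
  int isnap = 0;
  auto record = [&](int step) {
    double ek = 0.0;
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k) {
        ek += 0.5 * E.mass * E.v[3 * i + k] * E.v[3 * i + k];
        ek += 0.5 * E.Lb[3 * i + k] * E.Lb[3 * i + k] / E.I[k];
      }
    }
    snap_t[isnap] = t0 + step * dt;
    snap_epot[isnap] = E.epot;
    snap_ekin[isnap] = ek;
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k) {
        sx[(size_t)isnap * E.N * 3 + 3 * i + k] = E.x[3 * i + k];
        sim[(size_t)isnap * E.N * 3 + 3 * i + k] = E.image[3 * i + k];
      }
      for (int k = 0; k < 4; ++k)
        sq[(size_t)isnap * E.N * 4 + 4 * i + k] = E.q[4 * i + k];
    }
    ++isnap;
  };
  record(0);

  double hdt = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick (body torque from world torque; rotation matrices are
    // still current from the last force evaluation)
    { PhaseTimer pt(&g_t_kick);
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k)
        E.v[3 * i + k] += hdt * E.F[3 * i + k] / E.mass;
      const double* R = &E.Rmat[9 * i];
      for (int k = 0; k < 3; ++k) {
        double tb = R[0 + k] * E.Tau[3 * i] + R[3 + k] * E.Tau[3 * i + 1] +
                    R[6 + k] * E.Tau[3 * i + 2];
        E.Lb[3 * i + k] += hdt * tb;
      }
    }
    }
    // A: half drift
    { PhaseTimer pt(&g_t_drift);
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k) E.x[3 * i + k] += hdt * E.v[3 * i + k];
      E.wrap(i);
      E.free_rotor(i, hdt);
    } }
    // O: friction + noise
    { PhaseTimer pt(&g_t_noise);
    if (gamma > 0 || gamma_rot[0] > 0) {
      for (int i = 0; i < E.N; ++i) {
        for (int k = 0; k < 3; ++k)
          E.v[3 * i + k] = c1t * E.v[3 * i + k] + c2t * rng.normal();
        for (int k = 0; k < 3; ++k)
          E.Lb[3 * i + k] = c1r[k] * E.Lb[3 * i + k] + c2r[k] * rng.normal();
      }
    } }
    // A: half drift
    { PhaseTimer pt(&g_t_drift);
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k) E.x[3 * i + k] += hdt * E.v[3 * i + k];
      E.wrap(i);
      E.free_rotor(i, hdt);
      renorm_quat(&E.q[4 * i]);
    } }
    // force evaluation and closing half kick
    E.forces();
    { PhaseTimer pt(&g_t_kick);
    for (int i = 0; i < E.N; ++i) {
      for (int k = 0; k < 3; ++k)
        E.v[3 * i + k] += hdt * E.F[3 * i + k] / E.mass;
      const double* R = &E.Rmat[9 * i];
      for (int k = 0; k < 3; ++k) {
        double tb = R[0 + k] * E.Tau[3 * i] + R[3 + k] * E.Tau[3 * i + 1] +
                    R[6 + k] * E.Tau[3 * i + 2];
        E.Lb[3 * i + k] += hdt * tb;
      }
    } }
    if (step % snap_stride == 0 || step == n_steps) {
      if (!std::isfinite(E.epot) || std::fabs(E.epot) > 1e6) {
        stop("unstable timestep: |potential energy| diverged (%.3g)", E.epot);
      }
      record(step);
      if (step % (snap_stride * 8) == 0) Rcpp::checkUserInterrupt();
    }
  }

  int used = isnap;
  NumericMatrix xf(E.N, 3), vf(E.N, 3), qf(E.N, 4), Lf(E.N, 3);
  IntegerMatrix imf(E.N, 3);
  for (int i = 0; i < E.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      xf(i, k) = E.x[3 * i + k]; vf(i, k) = E.v[3 * i + k];
      Lf(i, k) = E.Lb[3 * i + k]; imf(i, k) = E.image[3 * i + k];
    }
    for (int k = 0; k < 4; ++k) qf(i, k) = E.q[4 * i + k];
  }
  return List::create(
    _["n_frames"] = used,
    _["times"] = snap_t, _["epot"] = snap_epot, _["ekin"] = snap_ekin,
    _["snap_x"] = sx, _["snap_q"] = sq, _["snap_image"] = sim,
    _["x"] = xf, _["v"] = vf, _["q"] = qf, _["Lb"] = Lf, _["image"] = imf);
}
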