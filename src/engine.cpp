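// Minimal classical MD core: harmonic bonds/angles, cosine torsions,
// harmonic impropers, shifted LJ + Coulomb under the minimum-image
// convention, velocity-Verlet integration, a collisional thermostat and
// constant-velocity spring steering (terminal-atom and center-of-mass
// modes) with a zero-velocity center-of-mass restraint.
//
// Units: length A, time ps, mass Da, energy kcal/mol.
// FCONV converts (kcal/mol/A)/Da to A/ps^2; KB is Boltzmann's constant
// in Da*A^2/ps^2/K so that var(v_x) = KB*T/m for Maxwell velocities.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const double FCONV = 418.4;      // kcal/mol/A/Da -> A/ps^2
static const double KB_MD = 0.83144626; // Da A^2 ps^-2 K^-1
static const double KCAL = 1.0 / FCONV; // Da A^2 ps^-2 -> kcal/mol

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

// deterministic RNG: xoshiro-free, plain mt19937_64 + Box-Muller
struct Rng {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { // in (0,1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

struct Topology {
  int n;
  std::vector<double> charge, eps, sigma, mass;
  std::vector<int> b_i, b_j;            std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;       std::vector<double> a_kf, a_t0;
  std::vector<int> t_i, t_j, t_k, t_l;  std::vector<double> t_v, t_n, t_g;
  std::vector<int> m_i, m_j, m_k, m_l;  std::vector<double> m_kf, m_x0;
  std::vector<std::vector<int> > excl;  // sorted per-atom exclusion lists
  int excl_span;                        // max |i - j| over exclusions
  double box[3];
  bool periodic;
  double cutoff, coulk;
};

// 1-based R indices -> 0-based
static void fill_int(std::vector<int>& v, SEXP s) {
  IntegerVector x(s);
  v.resize(x.size());
  for (int i = 0; i < x.size(); ++i) v[i] = x[i] - 1;
}
static void fill_dbl(std::vector<double>& v, SEXP s) {
  NumericVector x(s);
  v.assign(x.begin(), x.end());
}

static Topology make_topology(const List& top) {
  Topology T;
  fill_dbl(T.charge, top["charge"]);
  fill_dbl(T.eps, top["eps"]);
  fill_dbl(T.sigma, top["sigma"]);
  fill_dbl(T.mass, top["mass"]);
  T.n = static_cast<int>(T.mass.size());
  fill_int(T.b_i, top["bond_i"]); fill_int(T.b_j, top["bond_j"]);
  fill_dbl(T.b_k, top["bond_k"]); fill_dbl(T.b_r0, top["bond_r0"]);
  fill_int(T.a_i, top["angle_i"]); fill_int(T.a_j, top["angle_j"]);
  fill_int(T.a_k, top["angle_k"]);
  fill_dbl(T.a_kf, top["angle_kf"]); fill_dbl(T.a_t0, top["angle_t0"]);
  fill_int(T.t_i, top["tor_i"]); fill_int(T.t_j, top["tor_j"]);
  fill_int(T.t_k, top["tor_k"]); fill_int(T.t_l, top["tor_l"]);
  fill_dbl(T.t_v, top["tor_v"]); fill_dbl(T.t_n, top["tor_n"]);
  fill_dbl(T.t_g, top["tor_g"]);
  fill_int(T.m_i, top["imp_i"]); fill_int(T.m_j, top["imp_j"]);
  fill_int(T.m_k, top["imp_k"]); fill_int(T.m_l, top["imp_l"]);
  fill_dbl(T.m_kf, top["imp_kf"]); fill_dbl(T.m_x0, top["imp_x0"]);
  NumericVector bx = top["box"];
  T.box[0] = bx[0]; T.box[1] = bx[1]; T.box[2] = bx[2];
  T.periodic = as<bool>(top["periodic"]);
  T.cutoff = as<double>(top["cutoff"]);
  T.coulk = as<double>(top["coulk"]);
  IntegerMatrix ex = top["excl"]; // 2 columns, 1-based pairs
  T.excl.assign(T.n, std::vector<int>());
  T.excl_span = 0;
  for (int r = 0; r < ex.nrow(); ++r) {
    int i = ex(r, 0) - 1, j = ex(r, 1) - 1;
    T.excl[i].push_back(j);
    T.excl[j].push_back(i);
    T.excl_span = std::max(T.excl_span, std::abs(i - j));
  }
  for (int i = 0; i < T.n; ++i) std::sort(T.excl[i].begin(), T.excl[i].end());
  return T;
}

static inline bool excluded(const Topology& T, int i, int j) {
  const std::vector<int>& e = T.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

static inline Vec3 minimg(const Topology& T, Vec3 d) {
  if (T.periodic) {
    d.x -= T.box[0] * std::nearbyint(d.x / T.box[0]);
    d.y -= T.box[1] * std::nearbyint(d.y / T.box[1]);
    d.z -= T.box[2] * std::nearbyint(d.z / T.box[2]);
  }
  return d;
}

// energy components + forces; forces accumulated into f (kcal/mol/A)
static void compute_forces(const Topology& T, const std::vector<Vec3>& r,
                           std::vector<Vec3>& f, double* ecomp) {
  for (int c = 0; c < 6; ++c) ecomp[c] = 0.0;
  std::fill(f.begin(), f.end(), Vec3());

  // bonds: U = k (r - r0)^2
  for (size_t b = 0; b < T.b_i.size(); ++b) {
    int i = T.b_i[b], j = T.b_j[b];
    Vec3 d = minimg(T, r[i] - r[j]);
    double rn = d.norm();
    double dr = rn - T.b_r0[b];
    ecomp[0] += T.b_k[b] * dr * dr;
    double fmag = -2.0 * T.b_k[b] * dr / rn;
    f[i] = f[i] + d * fmag;
    f[j] = f[j] - d * fmag;
  }

  // angles: U = k (theta - theta0)^2
  for (size_t a = 0; a < T.a_i.size(); ++a) {
    int i = T.a_i[a], j = T.a_j[a], k = T.a_k[a];
    Vec3 va = minimg(T, r[i] - r[j]);
    Vec3 vb = minimg(T, r[k] - r[j]);
    double na = va.norm(), nb = vb.norm();
    double ct = va.dot(vb) / (na * nb);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dth = th - T.a_t0[a];
    ecomp[1] += T.a_kf[a] * dth * dth;
    double dudth = 2.0 * T.a_kf[a] * dth;
    Vec3 ua = va * (1.0 / na), ub = vb * (1.0 / nb);
    Vec3 dthdri = (ua * ct - ub) * (1.0 / (na * st));
    Vec3 dthdrk = (ub * ct - ua) * (1.0 / (nb * st));
    f[i] = f[i] - dthdri * dudth;
    f[k] = f[k] - dthdrk * dudth;
    f[j] = f[j] + (dthdri + dthdrk) * dudth;
  }

  // proper torsions: U = (V/2)(1 + cos(n phi - gamma))
  // impropers:       U = k (wrap(phi - x0))^2, same geometry
  size_t nt = T.t_i.size(), nm = T.m_i.size();
  for (size_t t = 0; t < nt + nm; ++t) {
    bool imp = t >= nt;
    size_t u = imp ? t - nt : t;
    int i = imp ? T.m_i[u] : T.t_i[u];
    int j = imp ? T.m_j[u] : T.t_j[u];
    int k = imp ? T.m_k[u] : T.t_k[u];
    int l = imp ? T.m_l[u] : T.t_l[u];
    Vec3 b1 = minimg(T, r[j] - r[i]);
    Vec3 b2 = minimg(T, r[k] - r[j]);
    Vec3 b3 = minimg(T, r[l] - r[k]);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double nb2 = b2.norm();
    double n1sq = n1.norm2(), n2sq = n2.norm2();
    if (n1sq < 1e-12 || n2sq < 1e-12) continue; // collinear, undefined
    double phi = std::atan2(n1.cross(n2).dot(b2) / nb2, n1.dot(n2));
    double dudphi;
    if (imp) {
      double dphi = phi - T.m_x0[u];
      while (dphi > M_PI) dphi -= 2 * M_PI;
      while (dphi < -M_PI) dphi += 2 * M_PI;
      ecomp[3] += T.m_kf[u] * dphi * dphi;
      dudphi = 2.0 * T.m_kf[u] * dphi;
    } else {
      double nn = T.t_n[u];
      ecomp[2] += 0.5 * T.t_v[u] * (1.0 + std::cos(nn * phi - T.t_g[u]));
      dudphi = -0.5 * T.t_v[u] * nn * std::sin(nn * phi - T.t_g[u]);
    }
    // dphi/dri = -(|b2|/|n1|^2) n1, dphi/drl = +(|b2|/|n2|^2) n2;
    // middle atoms by the chain rule through b1.b2/|b2|^2 projections
    Vec3 fi = n1 * (dudphi * nb2 / n1sq);
    Vec3 fl = n2 * (-dudphi * nb2 / n2sq);
    double c1 = b1.dot(b2) / b2.norm2();
    double c2 = b3.dot(b2) / b2.norm2();
    Vec3 fj = fi * (-(1.0 + c1)) + fl * c2;
    Vec3 fk = fi * c1 - fl * (1.0 + c2);
    f[i] = f[i] + fi;
    f[j] = f[j] + fj;
    f[k] = f[k] + fk;
    f[l] = f[l] + fl;
  }

  // nonbonded: shifted LJ + shifted Coulomb, minimum image, cutoff
  double rc = T.cutoff, rc2 = rc * rc;
  for (int i = 0; i < T.n - 1; ++i) {
    for (int j = i + 1; j < T.n; ++j) {
      Vec3 d = minimg(T, r[i] - r[j]);
      double r2 = d.norm2();
      if (r2 >= rc2) continue;
      if (j - i <= T.excl_span && excluded(T, i, j)) continue;
      double fmag = 0.0;
      double epsij = std::sqrt(T.eps[i] * T.eps[j]);
      if (epsij > 0) {
        if (r2 < 0.01) {  // < 0.1 A between LJ sites: unphysical overlap
          stop("atoms %d and %d overlap (nonbonded distance %.4f A)",
               i + 1, j + 1, std::sqrt(r2));
        }
        double sij = 0.5 * (T.sigma[i] + T.sigma[j]);
        double s2 = sij * sij;
        double a = s2 / r2;
        double sr6 = a * a * a;
        double sr12 = sr6 * sr6;
        double b = s2 / rc2;
        double src6 = b * b * b;
        ecomp[4] += 4.0 * epsij * (sr12 - sr6) -
                    4.0 * epsij * (src6 * src6 - src6);
        fmag += 24.0 * epsij * (2.0 * sr12 - sr6) / r2;
      }
      double qq = T.charge[i] * T.charge[j];
      if (qq != 0.0) {
        double rn = std::sqrt(r2);
        ecomp[5] += T.coulk * qq * (1.0 / rn - 1.0 / rc);
        fmag += T.coulk * qq / (r2 * rn);
      }
      f[i] = f[i] + d * fmag;
      f[j] = f[j] - d * fmag;
    }
  }
}

struct Steering {
  int mode;                 // 0 none, 1 terminal atom, 2 center of mass
  std::vector<int> idx;     // 0-based atom indices
  double k;                 // kcal/mol/A^2
  Vec3 dir;                 // unit pulling direction
  double v;                 // wall velocity A/ps along dir
  double x0;                // wall coordinate at t = 0 (projection on dir)
  double gmass;             // total mass of the group
};

static Steering make_steering(const List& s, const std::vector<double>& mass) {
  Steering st;
  st.mode = as<int>(s["mode"]);
  if (st.mode == 0) { st.k = 0; st.v = 0; st.x0 = 0; st.gmass = 1; return st; }
  IntegerVector ii = s["idx"];
  for (int q = 0; q < ii.size(); ++q) st.idx.push_back(ii[q] - 1);
  st.k = as<double>(s["k"]);
  NumericVector dd = s["dir"];
  st.dir = Vec3(dd[0], dd[1], dd[2]);
  st.v = as<double>(s["v"]);
  st.x0 = as<double>(s["x0"]);
  st.gmass = 0.0;
  for (size_t q = 0; q < st.idx.size(); ++q) st.gmass += mass[st.idx[q]];
  return st;
}

// attachment coordinate: projection on dir of terminal atom or group COM
static double attach_coord(const Steering& st, const std::vector<Vec3>& r,
                           const std::vector<double>& mass) {
  if (st.mode == 1) return r[st.idx[0]].dot(st.dir);
  double s = 0.0;
  for (size_t q = 0; q < st.idx.size(); ++q) {
    s += mass[st.idx[q]] * r[st.idx[q]].dot(st.dir);
  }
  return s / st.gmass;
}

// add spring force; returns signed spring force k*dx (kcal/mol/A)
static double apply_steering(const Steering& st, const std::vector<Vec3>& r,
                             const std::vector<double>& mass, double t,
                             std::vector<Vec3>& f) {
  if (st.mode == 0) return 0.0;
  double wall = st.x0 + st.v * t;
  double dx = wall - attach_coord(st, r, mass);
  double fs = st.k * dx;
  if (st.mode == 1) {
    f[st.idx[0]] = f[st.idx[0]] + st.dir * fs;
  } else {
    for (size_t q = 0; q < st.idx.size(); ++q) {
      int i = st.idx[q];
      f[i] = f[i] + st.dir * (fs * mass[i] / st.gmass);
    }
  }
  return fs;
}

// [[Rcpp::export(name = ".cpp_energy_forces")]]
List cpp_energy_forces(NumericMatrix pos, List top) {
  Topology T = make_topology(top);
  std::vector<Vec3> r(T.n), f(T.n);
  for (int i = 0; i < T.n; ++i) r[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  double e[6];
  compute_forces(T, r, f, e);
  NumericMatrix F(T.n, 3);
  for (int i = 0; i < T.n; ++i) { F(i,0)=f[i].x; F(i,1)=f[i].y; F(i,2)=f[i].z; }
  return List::create(
    _["bond"] = e[0], _["angle"] = e[1], _["torsion"] = e[2],
    _["improper"] = e[3], _["vdw"] = e[4], _["coulomb"] = e[5],
    _["potential"] = e[0] + e[1] + e[2] + e[3] + e[4] + e[5],
    _["forces"] = F);
}

// [[Rcpp::export(name = ".cpp_run_md")]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, List top,
                double dt, int nsteps, int sample_every,
                double temperature, double coll_freq, double coll_mass,
                double seed, List pull, List restr, int snapshot_every) {
  Topology T = make_topology(top);
  int n = T.n;
  std::vector<Vec3> r(n), v(n), f(n), fnew(n);
  for (int i = 0; i < n; ++i) {
    r[i] = Vec3(pos(i,0), pos(i,1), pos(i,2));
    v[i] = Vec3(vel(i,0), vel(i,1), vel(i,2));
  }
  Steering sp = make_steering(pull, T.mass);
  Steering sr = make_steering(restr, T.mass);
  Rng rng(static_cast<uint64_t>(seed));

  double e[6];
  compute_forces(T, r, f, e);
  double t = 0.0;
  apply_steering(sp, r, T.mass, t, f);
  apply_steering(sr, r, T.mass, t, f);

  int nsamp = nsteps / sample_every;
  NumericVector s_t(nsamp), s_fp(nsamp), s_fr(nsamp), s_com(nsamp),
                s_ke(nsamp), s_pe(nsamp);
  int nsnap = snapshot_every > 0 ? nsteps / snapshot_every : 0;
  NumericVector snaps(nsnap > 0 ? nsnap * n * 3 : 0);
  int isamp = 0, isnap = 0;
  double pcoll = coll_freq * dt;

  for (int step = 1; step <= nsteps; ++step) {
    // velocity Verlet
    for (int i = 0; i < n; ++i) {
      double am = 0.5 * dt * FCONV / T.mass[i];
      v[i] = v[i] + f[i] * am;
      r[i] = r[i] + v[i] * dt;
    }
    t = step * dt;
    compute_forces(T, r, fnew, e);
    double fp = apply_steering(sp, r, T.mass, t, fnew);
    double fr = apply_steering(sr, r, T.mass, t, fnew);
    for (int i = 0; i < n; ++i) {
      double am = 0.5 * dt * FCONV / T.mass[i];
      v[i] = v[i] + fnew[i] * am;
    }
    std::swap(f, fnew);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(r[i].x) || !std::isfinite(r[i].y) ||
          !std::isfinite(r[i].z)) {
        stop("non-finite coordinate for atom %d at step %d "
             "(overlapping atoms or too large a time step)", i + 1, step);
      }
    }
    // collisional thermostat: elastic collision with Maxwell virtual particle
    if (coll_freq > 0 && temperature > 0) {
      double sv = std::sqrt(KB_MD * temperature / coll_mass);
      for (int i = 0; i < n; ++i) {
        if (rng.unif() < pcoll) {
          Vec3 u(sv * rng.norm(), sv * rng.norm(), sv * rng.norm());
          double m = T.mass[i], m0 = coll_mass;
          double a = (m - m0) / (m + m0), b = 2.0 * m0 / (m + m0);
          v[i] = v[i] * a + u * b;
        }
      }
    }
    if (step % sample_every == 0 && isamp < nsamp) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) ke += 0.5 * T.mass[i] * v[i].norm2();
      s_t[isamp] = t;
      s_fp[isamp] = fp;
      s_fr[isamp] = fr;
      s_com[isamp] = sp.mode > 0 ? attach_coord(sp, r, T.mass) : 0.0;
      s_ke[isamp] = ke * KCAL;
      s_pe[isamp] = e[0] + e[1] + e[2] + e[3] + e[4] + e[5];
      ++isamp;
    }
    if (snapshot_every > 0 && step % snapshot_every == 0 && isnap < nsnap) {
      for (int i = 0; i < n; ++i) {
        snaps[(static_cast<size_t>(isnap) * n + i) * 3 + 0] = r[i].x;
        snaps[(static_cast<size_t>(isnap) * n + i) * 3 + 1] = r[i].y;
        snaps[(static_cast<size_t>(isnap) * n + i) * 3 + 2] = r[i].z;
      }
      ++isnap;
    }
  }

  NumericMatrix R(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    R(i,0)=r[i].x; R(i,1)=r[i].y; R(i,2)=r[i].z;
    V(i,0)=v[i].x; V(i,1)=v[i].y; V(i,2)=v[i].z;
  }
  return List::create(
    _["pos"] = R, _["vel"] = V,
    _["time"] = s_t, _["f_pull"] = s_fp, _["f_restraint"] = s_fr,
    _["com_coord"] = s_com, _["kinetic"] = s_ke, _["potential"] = s_pe,
    _["snapshots"] = snaps, _["n_snapshots"] = isnap);
}

// [[Rcpp::export(name = ".cpp_steering_forces")]]
NumericMatrix cpp_steering_forces(NumericMatrix pos, NumericVector mass,
                                  List spec, double t) {
  std::vector<double> m(mass.begin(), mass.end());
  int n = pos.nrow();
  std::vector<Vec3> r(n), f(n);
  for (int i = 0; i < n; ++i) r[i] = Vec3(pos(i,0), pos(i,1), pos(i,2));
  Steering st = make_steering(spec, m);
  apply_steering(st, r, m, t, f);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0)=f[i].x; F(i,1)=f[i].y; F(i,2)=f[i].z; }
  return F;
}
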