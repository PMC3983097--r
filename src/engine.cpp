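// Molecular dynamics core: Dreiding-form energies/forces, velocity-Verlet
// integration with a single Nose-Hoover thermostat, cell-based neighbor
// list with Verlet skin, harmonic point restraints and a one-sided wall.
//
// Units: length Angstrom, time fs, energy kcal/mol, mass amu, temperature K.
// 1 kcal/mol = FCONV amu A^2 fs^-2.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double FCONV = 4.184e-4;    // kcal/mol in amu A^2 fs^-2
static const double KBOLTZ = 0.0019872041; // kcal/mol/K
static const double HARD_FLOOR = 0.1;    // A; below this two nonbonded atoms overlap

struct Vec3 { double x, y, z; };

static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 c;
  c.x = a.y * b.z - a.z * b.y;
  c.y = a.z * b.x - a.x * b.z;
  c.z = a.x * b.y - a.y * b.x;
  return c;
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

class Engine {
public:
  int n, ntype;
  std::vector<double> x, v, f, mass, invmass;
  std::vector<int> type;
  std::vector<char> frozen;
  int nfree, gdof;

  // bonded terms (0-based atom indices)
  std::vector<int> b_i, b_j;
  std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_kv, a_t0;
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_A1, d_A2, d_A3;

  // nonbonded
  std::vector<double> Atab, Ctab, Ushift; // ntype x ntype, row-major
  double cutoff, skin;
  bool shift_lj;
  std::unordered_set<int64_t> excl;

  // restraints
  std::vector<int> r_atom;
  std::vector<double> r_tx, r_ty, r_tz, r_k;

  // wall
  bool wall_on;
  double wall_z, wall_k;

  // thermostat
  bool nvt;
  double T_target, tau, xi, eta;

  // neighbor list
  std::vector<int> nl_i, nl_j;
  std::vector<double> x_ref;
  long n_rebuilds;

  // energy decomposition of last force evaluation
  double e_bond, e_angle, e_dih, e_nb, e_rest, e_wall;

  Engine() : wall_on(false), nvt(false), xi(0.0), eta(0.0), n_rebuilds(0) {}

  inline int64_t pkey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (int64_t)i * (int64_t)n + (int64_t)j;
  }

  void buildNeighborList() {
    const double rl = cutoff + skin, rl2 = rl * rl;
    nl_i.clear();
    nl_j.clear();
    // bounding box
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double c = x[3 * i + d];
        if (c < lo[d]) lo[d] = c;
        if (c > hi[d]) hi[d] = c;
      }
    int nc[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / rl));
      if (nc[d] > 64) nc[d] = 64;
    }
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), next(n, -1), cellof(n);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double w = (hi[d] - lo[d]) / nc[d];
        int k = w > 0 ? (int)((x[3 * i + d] - lo[d]) / w) : 0;
        if (k < 0) k = 0;
        if (k >= nc[d]) k = nc[d] - 1;
        c[d] = k;
      }
      int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      cellof[i] = ci;
      next[i] = head[ci];
      head[ci] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int ci = (cz * nc[1] + cy) * nc[0] + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ox = cx + dx, oy = cy + dy, oz = cz + dz;
                if (ox < 0 || oy < 0 || oz < 0 || ox >= nc[0] || oy >= nc[1] ||
                    oz >= nc[2])
                  continue;
                int cj = (oz * nc[1] + oy) * nc[0] + ox;
                if (cj < ci) continue; // each cell pair once
                for (int i = head[ci]; i != -1; i = next[i]) {
                  int jstart = (ci == cj) ? next[i] : head[cj];
                  for (int j = jstart; j != -1; j = next[j]) {
                    if (frozen[i] && frozen[j]) continue;
                    double ddx = x[3 * i] - x[3 * j];
                    double ddy = x[3 * i + 1] - x[3 * j + 1];
                    double ddz = x[3 * i + 2] - x[3 * j + 2];
                    double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    if (r2 > rl2) continue;
                    if (excl.count(pkey(i, j))) continue;
                    if (i < j) {
                      nl_i.push_back(i);
                      nl_j.push_back(j);
                    } else {
                      nl_i.push_back(j);
                      nl_j.push_back(i);
                    }
                  }
                }
              }
        }
    x_ref = x;
    ++n_rebuilds;
  }

  bool listStale() const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double ddx = x[3 * i] - x_ref[3 * i];
      double ddy = x[3 * i + 1] - x_ref[3 * i + 1];
      double ddz = x[3 * i + 2] - x_ref[3 * i + 2];
      if (ddx * ddx + ddy * ddy + ddz * ddz > lim2) return true;
    }
    return false;
  }

  // full energy + forces at current x
  double forces() {
    std::fill(f.begin(), f.end(), 0.0);
    e_bond = e_angle = e_dih = e_nb = e_rest = e_wall = 0.0;

    // bonds: U = k (r - r0)^2
    for (size_t t = 0; t < b_i.size(); ++t) {
      int i = b_i[t], j = b_j[t];
      Vec3 d = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                x[3 * i + 2] - x[3 * j + 2]};
      double r = norm(d);
      if (r <= 0) stop("bond with zero length between atoms %d and %d", i + 1, j + 1);
      double dr = r - b_r0[t];
      e_bond += b_k[t] * dr * dr;
      double fac = -2.0 * b_k[t] * dr / r;
      f[3 * i] += fac * d.x; f[3 * i + 1] += fac * d.y; f[3 * i + 2] += fac * d.z;
      f[3 * j] -= fac * d.x; f[3 * j + 1] -= fac * d.y; f[3 * j + 2] -= fac * d.z;
    }

    // angles: U = kv (theta - theta0)^2, j is the center
    for (size_t t = 0; t < a_i.size(); ++t) {
      int i = a_i[t], j = a_j[t], k = a_k[t];
      Vec3 rij = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                  x[3 * i + 2] - x[3 * j + 2]};
      Vec3 rkj = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                  x[3 * k + 2] - x[3 * j + 2]};
      double nij = norm(rij), nkj = norm(rkj);
      double ct = dot(rij, rkj) / (nij * nkj);
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double theta = std::acos(ct);
      double dth = theta - a_t0[t];
      e_angle += a_kv[t] * dth * dth;
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) continue; // collinear: force direction undefined
      double dU = 2.0 * a_kv[t] * dth;
      double ci = dU / (nij * st), ck = dU / (nkj * st);
      Vec3 ei = {rij.x / nij, rij.y / nij, rij.z / nij};
      Vec3 ek = {rkj.x / nkj, rkj.y / nkj, rkj.z / nkj};
      Vec3 fi = {ci * (ek.x - ct * ei.x), ci * (ek.y - ct * ei.y),
                 ci * (ek.z - ct * ei.z)};
      Vec3 fk = {ck * (ei.x - ct * ek.x), ck * (ei.y - ct * ek.y),
                 ck * (ei.z - ct * ek.z)};
      f[3 * i] += fi.x; f[3 * i + 1] += fi.y; f[3 * i + 2] += fi.z;
      f[3 * k] += fk.x; f[3 * k + 1] += fk.y; f[3 * k + 2] += fk.z;
      f[3 * j] -= fi.x + fk.x; f[3 * j + 1] -= fi.y + fk.y; f[3 * j + 2] -= fi.z + fk.z;
    }

    // dihedrals: U = 0.5[A1(1+cos p) + A2(1-cos 2p) + A3(1+cos 3p)]
    for (size_t t = 0; t < d_i.size(); ++t) {
      int i = d_i[t], j = d_j[t], k = d_k[t], l = d_l[t];
      Vec3 b1 = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1], x[3 * j + 2] - x[3 * i + 2]};
      Vec3 b2 = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1], x[3 * k + 2] - x[3 * j + 2]};
      Vec3 b3 = {x[3 * l] - x[3 * k], x[3 * l + 1] - x[3 * k + 1], x[3 * l + 2] - x[3 * k + 2]};
      Vec3 c1 = cross(b1, b2), c2 = cross(b2, b3);
      double nb2 = norm(b2), nc1s = dot(c1, c1), nc2s = dot(c2, c2);
      if (nc1s < 1e-12 || nc2s < 1e-12) continue;
      double sphi = dot(cross(c1, c2), b2) / nb2;
      double cphi = dot(c1, c2);
      double phi = std::atan2(sphi, cphi);
      double cp = std::cos(phi), c2p = std::cos(2 * phi), c3p = std::cos(3 * phi);
      e_dih += 0.5 * (d_A1[t] * (1 + cp) + d_A2[t] * (1 - c2p) + d_A3[t] * (1 + c3p));
      double dU = 0.5 * (-d_A1[t] * std::sin(phi) + 2 * d_A2[t] * std::sin(2 * phi) -
                         3 * d_A3[t] * std::sin(3 * phi));
      // standard torsion gradient decomposition (verified against central
      // differences): end forces along the plane normals, inner atoms by
      // projection bookkeeping so total force and torque vanish
      double gi = dU * nb2 / nc1s, gl = -dU * nb2 / nc2s;
      Vec3 Fi = {gi * c1.x, gi * c1.y, gi * c1.z};
      Vec3 Fl = {gl * c2.x, gl * c2.y, gl * c2.z};
      double t1 = dot(b1, b2) / (nb2 * nb2), t2 = dot(b3, b2) / (nb2 * nb2);
      Vec3 Fj = {-Fi.x - t1 * Fi.x + t2 * Fl.x, -Fi.y - t1 * Fi.y + t2 * Fl.y,
                 -Fi.z - t1 * Fi.z + t2 * Fl.z};
      Vec3 Fk = {-Fl.x + t1 * Fi.x - t2 * Fl.x, -Fl.y + t1 * Fi.y - t2 * Fl.y,
                 -Fl.z + t1 * Fi.z - t2 * Fl.z};
      f[3 * i] += Fi.x; f[3 * i + 1] += Fi.y; f[3 * i + 2] += Fi.z;
      f[3 * j] += Fj.x; f[3 * j + 1] += Fj.y; f[3 * j + 2] += Fj.z;
      f[3 * k] += Fk.x; f[3 * k + 1] += Fk.y; f[3 * k + 2] += Fk.z;
      f[3 * l] += Fl.x; f[3 * l + 1] += Fl.y; f[3 * l + 2] += Fl.z;
    }

    // nonbonded 12-6 (energy-shifted to zero at the cutoff)
    const double rc2 = cutoff * cutoff;
    for (size_t t = 0; t < nl_i.size(); ++t) {
      int i = nl_i[t], j = nl_j[t];
      double ddx = x[3 * i] - x[3 * j];
      double ddy = x[3 * i + 1] - x[3 * j + 1];
      double ddz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 > rc2) continue;
      if (r2 < HARD_FLOOR * HARD_FLOOR)
        stop("overlapping atoms: nonbonded pair %d-%d at distance below %g A",
             i + 1, j + 1, HARD_FLOOR);
      int tt = type[i] * ntype + type[j];
      double inv2 = 1.0 / r2, inv6 = inv2 * inv2 * inv2;
      double A = Atab[tt], C = Ctab[tt];
      double u = (A * inv6 - C) * inv6;
      e_nb += u - (shift_lj ? Ushift[tt] : 0.0);
      double fac = (12.0 * A * inv6 - 6.0 * C) * inv6 * inv2;
      f[3 * i] += fac * ddx; f[3 * i + 1] += fac * ddy; f[3 * i + 2] += fac * ddz;
      f[3 * j] -= fac * ddx; f[3 * j + 1] -= fac * ddy; f[3 * j + 2] -= fac * ddz;
    }

    // harmonic point restraints: U = k |x - target|^2
    for (size_t t = 0; t < r_atom.size(); ++t) {
      int i = r_atom[t];
      double ddx = x[3 * i] - r_tx[t], ddy = x[3 * i + 1] - r_ty[t],
             ddz = x[3 * i + 2] - r_tz[t];
      e_rest += r_k[t] * (ddx * ddx + ddy * ddy + ddz * ddz);
      f[3 * i] -= 2.0 * r_k[t] * ddx;
      f[3 * i + 1] -= 2.0 * r_k[t] * ddy;
      f[3 * i + 2] -= 2.0 * r_k[t] * ddz;
    }

    // one-sided wall from above: U = kw (z - zw)^2 for z > zw
    if (wall_on) {
      for (int i = 0; i < n; ++i) {
        double dz = x[3 * i + 2] - wall_z;
        if (dz > 0) {
          e_wall += wall_k * dz * dz;
          f[3 * i + 2] -= 2.0 * wall_k * dz;
        }
      }
    }

    return e_bond + e_angle + e_dih + e_nb + e_rest + e_wall;
  }

  double kinetic() const {
    double k = 0.0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      k += mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                      v[3 * i + 2] * v[3 * i + 2]);
    }
    return 0.5 * k / FCONV; // kcal/mol
  }

  void checkFinite(long step) const {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(x[3 * i + d]) || !std::isfinite(v[3 * i + d]))
          stop("numerical blowup at step %ld: atom %d has non-finite position or velocity",
               step, i + 1);
  }
};

static Engine makeEngine(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                         LogicalVector frozen, IntegerVector type, int ntype,
                         NumericMatrix Atab, NumericMatrix Ctab, double cutoff,
                         double skin, bool shift_lj, IntegerMatrix bonds,
                         NumericVector b_k, NumericVector b_r0, IntegerMatrix angles,
                         NumericVector a_kv, NumericVector a_t0,
                         IntegerMatrix dihedrals, NumericMatrix dih_A,
                         IntegerMatrix excl, IntegerVector restr_atom,
                         NumericMatrix restr_target, NumericVector restr_k,
                         bool wall_on, double wall_z, double wall_k) {
  Engine E;
  E.n = pos.nrow();
  E.ntype = ntype;
  E.x.resize(3 * E.n);
  E.v.resize(3 * E.n);
  E.f.assign(3 * E.n, 0.0);
  E.mass.resize(E.n);
  E.invmass.resize(E.n);
  E.type.resize(E.n);
  E.frozen.resize(E.n);
  E.nfree = 0;
  for (int i = 0; i < E.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      E.x[3 * i + d] = pos(i, d);
      E.v[3 * i + d] = vel(i, d);
    }
    E.mass[i] = mass[i];
    E.invmass[i] = 1.0 / mass[i];
    E.type[i] = type[i]; // 0-based
    E.frozen[i] = frozen[i] ? 1 : 0;
    if (!E.frozen[i]) ++E.nfree;
    else { E.v[3 * i] = E.v[3 * i + 1] = E.v[3 * i + 2] = 0.0; }
  }
  E.gdof = 3 * E.nfree;

  int nb = bonds.nrow();
  E.b_i.resize(nb); E.b_j.resize(nb); E.b_k.resize(nb); E.b_r0.resize(nb);
  for (int t = 0; t < nb; ++t) {
    E.b_i[t] = bonds(t, 0) - 1; E.b_j[t] = bonds(t, 1) - 1;
    E.b_k[t] = b_k[t]; E.b_r0[t] = b_r0[t];
  }
  int na = angles.nrow();
  E.a_i.resize(na); E.a_j.resize(na); E.a_k.resize(na);
  E.a_kv.resize(na); E.a_t0.resize(na);
  for (int t = 0; t < na; ++t) {
    E.a_i[t] = angles(t, 0) - 1; E.a_j[t] = angles(t, 1) - 1;
    E.a_k[t] = angles(t, 2) - 1; E.a_kv[t] = a_kv[t]; E.a_t0[t] = a_t0[t];
  }
  int nd = dihedrals.nrow();
  E.d_i.resize(nd); E.d_j.resize(nd); E.d_k.resize(nd); E.d_l.resize(nd);
  E.d_A1.resize(nd); E.d_A2.resize(nd); E.d_A3.resize(nd);
  for (int t = 0; t < nd; ++t) {
    E.d_i[t] = dihedrals(t, 0) - 1; E.d_j[t] = dihedrals(t, 1) - 1;
    E.d_k[t] = dihedrals(t, 2) - 1; E.d_l[t] = dihedrals(t, 3) - 1;
    E.d_A1[t] = dih_A(t, 0); E.d_A2[t] = dih_A(t, 1); E.d_A3[t] = dih_A(t, 2);
  }

  E.Atab.resize(ntype * ntype);
  E.Ctab.resize(ntype * ntype);
  E.Ushift.resize(ntype * ntype);
  double rc6 = std::pow(cutoff, 6.0);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) {
      E.Atab[a * ntype + b] = Atab(a, b);
      E.Ctab[a * ntype + b] = Ctab(a, b);
      E.Ushift[a * ntype + b] = (Atab(a, b) / rc6 - Ctab(a, b)) / rc6;
    }
  E.cutoff = cutoff;
  E.skin = skin;
  E.shift_lj = shift_lj;
  for (int t = 0; t < excl.nrow(); ++t)
    E.excl.insert(E.pkey(excl(t, 0) - 1, excl(t, 1) - 1));

  int nr = restr_atom.size();
  E.r_atom.resize(nr); E.r_tx.resize(nr); E.r_ty.resize(nr); E.r_tz.resize(nr);
  E.r_k.resize(nr);
  for (int t = 0; t < nr; ++t) {
    E.r_atom[t] = restr_atom[t] - 1;
    E.r_tx[t] = restr_target(t, 0);
    E.r_ty[t] = restr_target(t, 1);
    E.r_tz[t] = restr_target(t, 2);
    E.r_k[t] = restr_k[t];
  }
  E.wall_on = wall_on;
  E.wall_z = wall_z;
  E.wall_k = wall_k;
  return E;
}

// [[Rcpp::export(name = ".engine_forces")]]
List engine_forces(NumericMatrix pos, NumericVector mass, LogicalVector frozen,
                   IntegerVector type, int ntype, NumericMatrix Atab,
                   NumericMatrix Ctab, double cutoff, double skin, bool shift_lj,
                   IntegerMatrix bonds, NumericVector b_k, NumericVector b_r0,
                   IntegerMatrix angles, NumericVector a_kv, NumericVector a_t0,
                   IntegerMatrix dihedrals, NumericMatrix dih_A, IntegerMatrix excl,
                   IntegerVector restr_atom, NumericMatrix restr_target,
                   NumericVector restr_k, bool wall_on, double wall_z,
                   double wall_k) {
  NumericMatrix vel(pos.nrow(), 3);
  Engine E = makeEngine(pos, vel, mass, frozen, type, ntype, Atab, Ctab, cutoff,
                        skin, shift_lj, bonds, b_k, b_r0, angles, a_kv, a_t0,
                        dihedrals, dih_A, excl, restr_atom, restr_target, restr_k,
                        wall_on, wall_z, wall_k);
  E.buildNeighborList();
  double etot = E.forces();
  NumericMatrix fout(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int d = 0; d < 3; ++d) fout(i, d) = E.f[3 * i + d];
  return List::create(
      _["bond"] = E.e_bond, _["angle"] = E.e_angle, _["dihedral"] = E.e_dih,
      _["nonbonded"] = E.e_nb, _["restraint"] = E.e_rest, _["wall"] = E.e_wall,
      _["total"] = etot, _["forces"] = fout);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                LogicalVector frozen, IntegerVector type, int ntype,
                NumericMatrix Atab, NumericMatrix Ctab, double cutoff, double skin,
                bool shift_lj, IntegerMatrix bonds, NumericVector b_k,
                NumericVector b_r0, IntegerMatrix angles, NumericVector a_kv,
                NumericVector a_t0, IntegerMatrix dihedrals, NumericMatrix dih_A,
                IntegerMatrix excl, IntegerVector restr_atom,
                NumericMatrix restr_target, NumericVector restr_k, bool wall_on,
                double wall_z, double wall_k, int n_steps, double dt,
                bool thermostat, double T_target, double tau, double xi0,
                double eta0, int report_every) {
  Engine E = makeEngine(pos, vel, mass, frozen, type, ntype, Atab, Ctab, cutoff,
                        skin, shift_lj, bonds, b_k, b_r0, angles, a_kv, a_t0,
                        dihedrals, dih_A, excl, restr_atom, restr_target, restr_k,
                        wall_on, wall_z, wall_k);
  E.nvt = thermostat;
  E.T_target = T_target;
  E.tau = tau;
  E.xi = xi0;
  E.eta = eta0;

  if (report_every < 1) report_every = n_steps > 0 ? n_steps : 1;
  int nframes = n_steps / report_every;
  NumericVector frames(Dimension(E.n, 3, nframes));
  int ncol_log = 12;
  NumericMatrix elog(nframes, ncol_log);

  const double gkT = E.gdof * KBOLTZ * T_target;
  const double Q = std::max(1e-12, gkT * tau * tau); // kcal/mol fs^2

  E.buildNeighborList();
  E.forces();

  int fr = 0;
  for (long step = 1; step <= n_steps; ++step) {
    if (E.nvt) {
      double K = E.kinetic();
      E.xi += 0.5 * dt * (2.0 * K - gkT) / Q;
      E.eta += 0.5 * dt * E.xi;
      double s = std::exp(-E.xi * 0.5 * dt);
      for (int i = 0; i < E.n; ++i)
        if (!E.frozen[i]) {
          E.v[3 * i] *= s; E.v[3 * i + 1] *= s; E.v[3 * i + 2] *= s;
        }
    }
    // half kick + drift
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      double a = 0.5 * dt * E.invmass[i] * FCONV;
      E.v[3 * i] += a * E.f[3 * i];
      E.v[3 * i + 1] += a * E.f[3 * i + 1];
      E.v[3 * i + 2] += a * E.f[3 * i + 2];
      E.x[3 * i] += dt * E.v[3 * i];
      E.x[3 * i + 1] += dt * E.v[3 * i + 1];
      E.x[3 * i + 2] += dt * E.v[3 * i + 2];
    }
    if (E.listStale()) E.buildNeighborList();
    double epot = E.forces();
    // second half kick
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      double a = 0.5 * dt * E.invmass[i] * FCONV;
      E.v[3 * i] += a * E.f[3 * i];
      E.v[3 * i + 1] += a * E.f[3 * i + 1];
      E.v[3 * i + 2] += a * E.f[3 * i + 2];
    }
    if (E.nvt) {
      double s = std::exp(-E.xi * 0.5 * dt);
      for (int i = 0; i < E.n; ++i)
        if (!E.frozen[i]) {
          E.v[3 * i] *= s; E.v[3 * i + 1] *= s; E.v[3 * i + 2] *= s;
        }
      double K = E.kinetic();
      E.eta += 0.5 * dt * E.xi;
      E.xi += 0.5 * dt * (2.0 * K - gkT) / Q;
    }

    if (step % 50 == 0 || step == n_steps) E.checkFinite(step);

    if (step % report_every == 0 && fr < nframes) {
      double K = E.kinetic();
      double Tinst = E.gdof > 0 ? 2.0 * K / (E.gdof * KBOLTZ) : 0.0;
      double cons = epot + K;
      if (E.nvt) cons += 0.5 * Q * E.xi * E.xi + gkT * E.eta;
      for (int i = 0; i < E.n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(size_t)fr * E.n * 3 + (size_t)d * E.n + i] = E.x[3 * i + d];
      elog(fr, 0) = step * dt;
      elog(fr, 1) = E.e_bond;
      elog(fr, 2) = E.e_angle;
      elog(fr, 3) = E.e_dih;
      elog(fr, 4) = E.e_nb;
      elog(fr, 5) = E.e_rest;
      elog(fr, 6) = E.e_wall;
      elog(fr, 7) = epot;
      elog(fr, 8) = K;
      elog(fr, 9) = Tinst;
      elog(fr, 10) = cons;
      elog(fr, 11) = E.xi;
      ++fr;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xout(E.n, 3), vout(E.n, 3), fout(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = E.x[3 * i + d];
      vout(i, d) = E.v[3 * i + d];
      fout(i, d) = E.f[3 * i + d];
    }
  colnames(elog) = CharacterVector::create(
      "time", "bond", "angle", "dihedral", "nonbonded", "restraint", "wall",
      "potential", "kinetic", "temperature", "conserved", "xi");
  return List::create(_["frames"] = frames, _["log"] = elog, _["x"] = xout,
                      _["v"] = vout, _["forces"] = fout, _["xi"] = E.xi,
                      _["eta"] = E.eta, _["n_rebuilds"] = E.n_rebuilds);
}

// [[Rcpp::export(name = ".engine_minimize")]]
List engine_minimize(NumericMatrix pos, NumericVector mass, LogicalVector frozen,
                     IntegerVector type, int ntype, NumericMatrix Atab,
                     NumericMatrix Ctab, double cutoff, double skin, bool shift_lj,
                     IntegerMatrix bonds, NumericVector b_k, NumericVector b_r0,
                     IntegerMatrix angles, NumericVector a_kv, NumericVector a_t0,
                     IntegerMatrix dihedrals, NumericMatrix dih_A,
                     IntegerMatrix excl, IntegerVector restr_atom,
                     NumericMatrix restr_target, NumericVector restr_k,
                     bool wall_on, double wall_z, double wall_k, int max_iter,
                     double ftol) {
  NumericMatrix vel(pos.nrow(), 3);
  Engine E = makeEngine(pos, vel, mass, frozen, type, ntype, Atab, Ctab, cutoff,
                        skin, shift_lj, bonds, b_k, b_r0, angles, a_kv, a_t0,
                        dihedrals, dih_A, excl, restr_atom, restr_target, restr_k,
                        wall_on, wall_z, wall_k);
  E.buildNeighborList();
  double e = E.forces();
  double alpha = 0.02; // A along the normalized steepest-descent direction
  std::vector<double> xold(E.x), fold(E.f);
  int it = 0;
  for (; it < max_iter; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      for (int d = 0; d < 3; ++d)
        fmax = std::max(fmax, std::fabs(E.f[3 * i + d]));
    }
    if (fmax < ftol) break;
    xold = E.x;
    fold = E.f;
    double scale = alpha / fmax;
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) E.x[3 * i + d] += scale * E.f[3 * i + d];
    }
    if (E.listStale()) E.buildNeighborList();
    double enew;
    try {
      enew = E.forces();
    } catch (...) {
      enew = R_PosInf;
    }
    if (enew < e) {
      e = enew;
      alpha = std::min(alpha * 1.2, 0.5);
    } else {
      E.x = xold;
      E.f = fold;
      alpha *= 0.5;
      if (alpha < 1e-8) break;
    }
  }
  NumericMatrix xout(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int d = 0; d < 3; ++d) xout(i, d) = E.x[3 * i + d];
  return List::create(_["x"] = xout, _["energy"] = e, _["iterations"] = it);
}
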