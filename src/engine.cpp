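// Coarse-grained bead-spring MD kernel: truncated-shifted LJ pairs with
// per-species cutoffs, harmonic/FENE bonds, harmonic angles, cosine
// dihedrals, cell-list neighbor search with Lees-Edwards sliding-brick
// boundaries, velocity-Verlet/BAOAB-Langevin integration, and virial
// bookkeeping. Reduced units: epsilon = sigma = m = kB = 1.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

// cast-based round-half-away: avoids libm rint/floor calls on pre-SSE4.1
// targets; arguments here are always a small number of box lengths
static inline double fast_round(double x) {
  return (double)(long long)(x + (x >= 0.0 ? 0.5 : -0.5));
}

static inline double wrap0L(double x, double L) {
  while (x < 0.0) x += L;
  while (x >= L) x -= L;
  return x;
}

// minimum image with Lees-Edwards x-offset tied to z-crossings
static inline void min_image(double& dx, double& dy, double& dz,
                             double Lx, double Ly, double Lz, double xshift) {
  double nz = fast_round(dz / Lz);
  dz -= nz * Lz;
  dx -= nz * xshift;
  dx -= Lx * fast_round(dx / Lx);
  dy -= Ly * fast_round(dy / Ly);
}

struct PairTables {
  int ns;
  std::vector<double> eps, rc2, ushift; // ns*ns
  double rcmax;
};

static PairTables make_tables(const NumericMatrix& eps, const NumericMatrix& rcut) {
  PairTables T;
  T.ns = eps.nrow();
  T.eps.resize(T.ns * T.ns);
  T.rc2.resize(T.ns * T.ns);
  T.ushift.resize(T.ns * T.ns);
  T.rcmax = 0.0;
  for (int a = 0; a < T.ns; ++a)
    for (int b = 0; b < T.ns; ++b) {
      double e = eps(a, b), rc = rcut(a, b);
      T.eps[a * T.ns + b] = e;
      T.rc2[a * T.ns + b] = rc * rc;
      double i6 = 1.0 / (rc * rc * rc * rc * rc * rc);
      T.ushift[a * T.ns + b] = 4.0 * e * (i6 * i6 - i6);
      if (e > 0.0 && rc > T.rcmax) T.rcmax = rc;
    }
  if (T.rcmax <= 0.0) T.rcmax = 1.0;
  return T;
}

typedef std::unordered_set<long long> ExclSet;

static ExclSet make_exclusions(const IntegerMatrix& bonds, int N) {
  ExclSet ex;
  for (int b = 0; b < bonds.nrow(); ++b) {
    long long i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    if (i > j) std::swap(i, j);
    ex.insert(i * (long long)N + j);
  }
  return ex;
}

// Enumerate unique pairs within `cut`, calling f(i, j, dx, dy, dz, r2).
// Positions must be wrapped into [0, L). Falls back to O(N^2) when the box
// is too small for a 3x3x3 cell stencil.
template <typename F>
static void for_each_pair(const std::vector<double>& px, const std::vector<double>& py,
                          const std::vector<double>& pz, double Lx, double Ly, double Lz,
                          double cut, double xshift, F f) {
  const int N = (int)px.size();
  const double cut2 = cut * cut;
  int ncx = (int)std::floor(Lx / cut), ncy = (int)std::floor(Ly / cut),
      ncz = (int)std::floor(Lz / cut);
  if (ncx < 3 || ncy < 3 || ncz < 3) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dz = pz[i] - pz[j];
        double nz = fast_round(dz / Lz);
        dz -= nz * Lz;
        if (dz * dz > cut2) continue;
        double dx = px[i] - px[j] - nz * xshift;
        dx -= Lx * fast_round(dx / Lx);
        if (dx * dx > cut2) continue;
        double dy = py[i] - py[j];
        dy -= Ly * fast_round(dy / Ly);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= cut2) f(i, j, dx, dy, dz, r2);
      }
    return;
  }
  const double clx = Lx / ncx, cly = Ly / ncy, clz = Lz / ncz;
  std::vector<int> head(ncx * ncy * ncz, -1), next(N, -1);
  std::vector<int> cix(N), ciy(N), ciz(N);
  for (int i = 0; i < N; ++i) {
    cix[i] = std::min((int)(px[i] / clx), ncx - 1);
    ciy[i] = std::min((int)(py[i] / cly), ncy - 1);
    ciz[i] = std::min((int)(pz[i] / clz), ncz - 1);
    int c = (ciz[i] * ncy + ciy[i]) * ncx + cix[i];
    next[i] = head[c]; head[c] = i;
  }
  for (int i = 0; i < N; ++i) {
    for (int dcz = -1; dcz <= 1; ++dcz) {
      int cz = ciz[i] + dcz;
      int wrapsgn = 0;
      if (cz < 0) { cz += ncz; wrapsgn = +1; }
      else if (cz >= ncz) { cz -= ncz; wrapsgn = -1; }
      // x-cell to center on, accounting for the sliding-brick offset of the
      // wrapped z-image
      int cxc;
      if (wrapsgn == 0) cxc = cix[i];
      else {
        double xs = wrap0L(px[i] + wrapsgn * xshift, Lx);
        cxc = std::min((int)(xs / clx), ncx - 1);
      }
      for (int dcy = -1; dcy <= 1; ++dcy) {
        int cy = ciy[i] + dcy;
        if (cy < 0) cy += ncy; else if (cy >= ncy) cy -= ncy;
        for (int dcx = -1; dcx <= 1; ++dcx) {
          int cx = cxc + dcx;
          if (cx < 0) cx += ncx; else if (cx >= ncx) cx -= ncx;
          int c = (cz * ncy + cy) * ncx + cx;
          for (int j = head[c]; j != -1; j = next[j]) {
            if (j <= i) continue;
            double dz = pz[i] - pz[j];
            double nz = fast_round(dz / Lz);
            dz -= nz * Lz;
            if (dz * dz > cut2) continue;
            double dx = px[i] - px[j] - nz * xshift;
            dx -= Lx * fast_round(dx / Lx);
            if (dx * dx > cut2) continue;
            double dy = py[i] - py[j];
            dy -= Ly * fast_round(dy / Ly);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 <= cut2) f(i, j, dx, dy, dz, r2);
          }
        }
      }
    }
  }
}

struct Topo {
  IntegerMatrix bonds; IntegerVector bond_kind;
  NumericVector bond_k, bond_l0;
  IntegerMatrix angles; NumericVector angle_k, angle_theta0;
  IntegerMatrix dihedrals; NumericVector dih_k, dih_d;
};

// full force/energy/virial evaluation; if nlist is non-null it supplies the
// candidate pairs (Verlet list built with a skin), otherwise pairs are
// enumerated fresh from a cell list
static double compute_forces(const std::vector<double>& px, const std::vector<double>& py,
                             const std::vector<double>& pz, const std::vector<int>& sp,
                             double Lx, double Ly, double Lz, const PairTables& T,
                             const Topo& topo, const ExclSet& excl, double xshift,
                             std::vector<double>& fx, std::vector<double>& fy,
                             std::vector<double>& fz, double vir[9],
                             const std::vector<std::pair<int, int> >* nlist = nullptr,
                             const std::vector<char>* has_excl = nullptr,
                             bool need_virial = true) {
  const int N = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (int k = 0; k < 9; ++k) vir[k] = 0.0;
  double pe = 0.0;
  const int ns = T.ns;

  auto kernel = [&](int i, int j, double dx, double dy, double dz, double r2) {
    int a = sp[i], b = sp[j];
    double e = T.eps[a * ns + b];
    if (e == 0.0) return;
    if (r2 > T.rc2[a * ns + b]) return;
    if (!excl.empty() && (!has_excl || ((*has_excl)[i] && (*has_excl)[j]))) {
      long long ii = i, jj = j;
      if (ii > jj) std::swap(ii, jj);
      if (excl.count(ii * (long long)N + jj)) return;
    }
    if (r2 < 1e-12) stop("singular overlap: pair distance ~ 0");
    double inv2 = 1.0 / r2;
    double i6 = inv2 * inv2 * inv2;
    pe += 4.0 * e * (i6 * i6 - i6) - T.ushift[a * ns + b];
    double fr = 24.0 * e * (2.0 * i6 * i6 - i6) * inv2; // f_over_r
    double fxi = fr * dx, fyi = fr * dy, fzi = fr * dz;
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
    fx[j] -= fxi; fy[j] -= fyi; fz[j] -= fzi;
    if (need_virial) {
      vir[0] += dx * fxi; vir[1] += dx * fyi; vir[2] += dx * fzi;
      vir[3] += dy * fxi; vir[4] += dy * fyi; vir[5] += dy * fzi;
      vir[6] += dz * fxi; vir[7] += dz * fyi; vir[8] += dz * fzi;
    }
  };

  if (nlist) {
    const double cut2 = T.rcmax * T.rcmax;
    for (size_t k = 0; k < nlist->size(); ++k) {
      int i = (*nlist)[k].first, j = (*nlist)[k].second;
      double dz = pz[i] - pz[j];
      double nz = fast_round(dz / Lz);
      dz -= nz * Lz;
      if (dz * dz > cut2) continue;
      double dx = px[i] - px[j] - nz * xshift;
      dx -= Lx * fast_round(dx / Lx);
      if (dx * dx > cut2) continue;
      double dy = py[i] - py[j];
      dy -= Ly * fast_round(dy / Ly);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= cut2) kernel(i, j, dx, dy, dz, r2);
    }
  } else {
    for_each_pair(px, py, pz, Lx, Ly, Lz, T.rcmax, xshift, kernel);
  }

  // bonds
  for (int b = 0; b < topo.bonds.nrow(); ++b) {
    int i = topo.bonds(b, 0) - 1, j = topo.bonds(b, 1) - 1;
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    min_image(dx, dy, dz, Lx, Ly, Lz, xshift);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double k = topo.bond_k[b], l0 = topo.bond_l0[b];
    double fmag; // dU/dl
    if (topo.bond_kind[b] == 0) {          // harmonic
      pe += 0.5 * k * (l - l0) * (l - l0);
      fmag = k * (l - l0);
    } else {                               // FENE
      if (l >= l0)
        stop("overstretched FENE bond: l = %f >= l0 = %f (bond %d)", l, l0, b + 1);
      double x2 = (l / l0) * (l / l0);
      pe += -0.5 * k * l0 * l0 * std::log(1.0 - x2);
      fmag = k * l / (1.0 - x2);
    }
    if (l > 1e-12) {
      double fr = -fmag / l; // force on i along +d
      double fxi = fr * dx, fyi = fr * dy, fzi = fr * dz;
      fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
      fx[j] -= fxi; fy[j] -= fyi; fz[j] -= fzi;
      vir[0] += dx * fxi; vir[1] += dx * fyi; vir[2] += dx * fzi;
      vir[3] += dy * fxi; vir[4] += dy * fyi; vir[5] += dy * fzi;
      vir[6] += dz * fxi; vir[7] += dz * fyi; vir[8] += dz * fzi;
    }
  }

  // angles: u = ri - rj, w = rk - rj (j central)
  for (int a = 0; a < topo.angles.nrow(); ++a) {
    int i = topo.angles(a, 0) - 1, j = topo.angles(a, 1) - 1, k = topo.angles(a, 2) - 1;
    double ux = px[i] - px[j], uy = py[i] - py[j], uz = pz[i] - pz[j];
    double wx = px[k] - px[j], wy = py[k] - py[j], wz = pz[k] - pz[j];
    min_image(ux, uy, uz, Lx, Ly, Lz, xshift);
    min_image(wx, wy, wz, Lx, Ly, Lz, xshift);
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lw = std::sqrt(wx * wx + wy * wy + wz * wz);
    double ct = (ux * wx + uy * wy + uz * wz) / (lu * lw);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    double ka = topo.angle_k[a], th0 = topo.angle_theta0[a];
    pe += 0.5 * ka * (th - th0) * (th - th0);
    double dudth = ka * (th - th0);
    // F_i = -dU/dth * dth/dri ; dth/dri = (ct*u/lu - w/lw) / (lu*st)
    double ci = -dudth / (lu * st);
    double fix = ci * (ct * ux / lu - wx / lw);
    double fiy = ci * (ct * uy / lu - wy / lw);
    double fiz = ci * (ct * uz / lu - wz / lw);
    double ck = -dudth / (lw * st);
    double fkx = ck * (ct * wx / lw - ux / lu);
    double fky = ck * (ct * wy / lw - uy / lu);
    double fkz = ck * (ct * wz / lw - uz / lu);
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
    fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    // virial relative to the central atom (sum of atom forces is zero)
    vir[0] += ux * fix + wx * fkx; vir[1] += ux * fiy + wx * fky; vir[2] += ux * fiz + wx * fkz;
    vir[3] += uy * fix + wy * fkx; vir[4] += uy * fiy + wy * fky; vir[5] += uy * fiz + wy * fkz;
    vir[6] += uz * fix + wz * fkx; vir[7] += uz * fiy + wz * fky; vir[8] += uz * fiz + wz * fkz;
  }

  // dihedrals: u_d = kd * (1 + d cos(phi)), IUPAC convention (cis: phi = 0)
  for (int q = 0; q < topo.dihedrals.nrow(); ++q) {
    int i = topo.dihedrals(q, 0) - 1, j = topo.dihedrals(q, 1) - 1,
        k = topo.dihedrals(q, 2) - 1, l = topo.dihedrals(q, 3) - 1;
    double b1x = px[j] - px[i], b1y = py[j] - py[i], b1z = pz[j] - pz[i];
    double b2x = px[k] - px[j], b2y = py[k] - py[j], b2z = pz[k] - pz[j];
    double b3x = px[l] - px[k], b3y = py[l] - py[k], b3z = pz[l] - pz[k];
    min_image(b1x, b1y, b1z, Lx, Ly, Lz, xshift);
    min_image(b2x, b2y, b2z, Lx, Ly, Lz, xshift);
    min_image(b3x, b3y, b3z, Lx, Ly, Lz, xshift);
    double mx = b1y * b2z - b1z * b2y, my = b1z * b2x - b1x * b2z, mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y, ny = b2z * b3x - b2x * b3z, nz = b2x * b3y - b2y * b3x;
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    double lb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (m2 < 1e-12 || n2 < 1e-12 || lb2 < 1e-12) continue; // collinear: torque-free
    double cphi = (mx * nx + my * ny + mz * nz) / std::sqrt(m2 * n2);
    cphi = std::max(-1.0, std::min(1.0, cphi));
    double sphi = (mx * b3x + my * b3y + mz * b3z) * lb2 / std::sqrt(m2 * n2);
    double phi = std::atan2(sphi, cphi);
    double kd = topo.dih_k[q], dd = topo.dih_d[q];
    pe += kd * (1.0 + dd * std::cos(phi));
    double dudphi = -kd * dd * std::sin(phi);
    // dphi/dri = -(|b2|/|m|^2) m, dphi/drl = (|b2|/|n|^2) n; middle atoms by
    // projection (verified against numerical gradients)
    double cfi = dudphi * lb2 / m2;
    double fix = cfi * mx, fiy = cfi * my, fiz = cfi * mz;
    double cfl = -dudphi * lb2 / n2;
    double flx = cfl * nx, fly = cfl * ny, flz = cfl * nz;
    double t1 = (b1x * b2x + b1y * b2y + b1z * b2z) / (lb2 * lb2);
    double t2 = (b3x * b2x + b3y * b2y + b3z * b2z) / (lb2 * lb2);
    double fjx = -(1 + t1) * fix + t2 * flx;
    double fjy = -(1 + t1) * fiy + t2 * fly;
    double fjz = -(1 + t1) * fiz + t2 * flz;
    double fkx2 = t1 * fix - (1 + t2) * flx;
    double fky2 = t1 * fiy - (1 + t2) * fly;
    double fkz2 = t1 * fiz - (1 + t2) * flz;
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[j] += fjx; fy[j] += fjy; fz[j] += fjz;
    fx[k] += fkx2; fy[k] += fky2; fz[k] += fkz2;
    fx[l] += flx; fy[l] += fly; fz[l] += flz;
    // virial relative to atom j: positions i, k, l relative to j
    double rix = -b1x, riy = -b1y, riz = -b1z;
    double rkx = b2x, rky = b2y, rkz = b2z;
    double rlx = b2x + b3x, rly = b2y + b3y, rlz = b2z + b3z;
    vir[0] += rix * fix + rkx * fkx2 + rlx * flx;
    vir[1] += rix * fiy + rkx * fky2 + rlx * fly;
    vir[2] += rix * fiz + rkx * fkz2 + rlx * flz;
    vir[3] += riy * fix + rky * fkx2 + rly * flx;
    vir[4] += riy * fiy + rky * fky2 + rly * fly;
    vir[5] += riy * fiz + rky * fkz2 + rly * flz;
    vir[6] += riz * fix + rkz * fkx2 + rlz * flx;
    vir[7] += riz * fiy + rkz * fky2 + rlz * fly;
    vir[8] += riz * fiz + rkz * fkz2 + rlz * flz;
  }

  for (int i = 0; i < N; ++i)
    if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) || !std::isfinite(fz[i]))
      stop("non-finite force on particle %d", i + 1);
  return pe;
}

static Topo topo_from_args(IntegerMatrix bonds, IntegerVector bond_kind,
                           NumericVector bond_k, NumericVector bond_l0,
                           IntegerMatrix angles, NumericVector angle_k,
                           NumericVector angle_theta0, IntegerMatrix dihedrals,
                           NumericVector dih_k, NumericVector dih_d) {
  Topo t;
  t.bonds = bonds; t.bond_kind = bond_kind; t.bond_k = bond_k; t.bond_l0 = bond_l0;
  t.angles = angles; t.angle_k = angle_k; t.angle_theta0 = angle_theta0;
  t.dihedrals = dihedrals; t.dih_k = dih_k; t.dih_d = dih_d;
  return t;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector species, NumericVector box,
                NumericMatrix eps, NumericMatrix rcut,
                IntegerMatrix bonds, IntegerVector bond_kind,
                NumericVector bond_k, NumericVector bond_l0,
                IntegerMatrix angles, NumericVector angle_k, NumericVector angle_theta0,
                IntegerMatrix dihedrals, NumericVector dih_k, NumericVector dih_d,
                double xshift) {
  const int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N);
  std::vector<int> sp(N);
  double Lx = box[0], Ly = box[1], Lz = box[2];
  for (int i = 0; i < N; ++i) {
    px[i] = wrap0L(pos(i, 0), Lx);
    py[i] = wrap0L(pos(i, 1), Ly);
    pz[i] = wrap0L(pos(i, 2), Lz);
    sp[i] = species[i] - 1;
  }
  PairTables T = make_tables(eps, rcut);
  Topo topo = topo_from_args(bonds, bond_kind, bond_k, bond_l0, angles, angle_k,
                             angle_theta0, dihedrals, dih_k, dih_d);
  ExclSet excl = make_exclusions(bonds, N);
  std::vector<double> fx(N), fy(N), fz(N);
  double vir[9];
  double pe = compute_forces(px, py, pz, sp, Lx, Ly, Lz, T, topo, excl, xshift,
                             fx, fy, fz, vir);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  NumericMatrix V(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) V(a, b) = vir[a * 3 + b];
  return List::create(_["forces"] = F, _["pe"] = pe, _["virial"] = V);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double cutoff, double xshift) {
  const int N = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> px(N), py(N), pz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = wrap0L(pos(i, 0), Lx);
    py[i] = wrap0L(pos(i, 1), Ly);
    pz[i] = wrap0L(pos(i, 2), Lz);
  }
  std::vector<int> vi, vj;
  for_each_pair(px, py, pz, Lx, Ly, Lz, cutoff, xshift,
    [&](int i, int j, double, double, double, double) {
      vi.push_back(i + 1); vj.push_back(j + 1);
    });
  IntegerMatrix out((int)vi.size(), 2);
  for (size_t k = 0; k < vi.size(); ++k) {
    out(k, 0) = std::min(vi[k], vj[k]);
    out(k, 1) = std::max(vi[k], vj[k]);
  }
  return out;
}

// mt19937_64-based standard normals via Box-Muller (platform-independent)
struct Gauss {
  std::mt19937_64 rng;
  bool have;
  double spare;
  Gauss(uint64_t seed) : rng(seed), have(false), spare(0.0) {}
  double unif() { return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    if (have) { have = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); have = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export]]
List cpp_run_chunk(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                   NumericVector box, NumericMatrix eps, NumericMatrix rcut,
                   IntegerMatrix bonds, IntegerVector bond_kind,
                   NumericVector bond_k, NumericVector bond_l0,
                   IntegerMatrix angles, NumericVector angle_k, NumericVector angle_theta0,
                   IntegerMatrix dihedrals, NumericVector dih_k, NumericVector dih_d,
                   int nsteps, double dt, int thermo_kind, double T_target,
                   double damping, double shear_rate, double xshift0,
                   bool thermo_transverse_only, double seed) {
  const int N = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  std::vector<int> sp(N);
  for (int i = 0; i < N; ++i) {
    px[i] = wrap0L(pos(i, 0), Lx);
    py[i] = wrap0L(pos(i, 1), Ly);
    pz[i] = wrap0L(pos(i, 2), Lz);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    sp[i] = species[i] - 1;
  }
  PairTables T = make_tables(eps, rcut);
  Topo topo = topo_from_args(bonds, bond_kind, bond_k, bond_l0, angles, angle_k,
                             angle_theta0, dihedrals, dih_k, dih_d);
  ExclSet excl = make_exclusions(bonds, N);
  std::vector<double> fx(N), fy(N), fz(N);
  double vir[9];
  double xshift = xshift0;
  const double dvx_wrap = shear_rate * Lz;
  Gauss gauss((uint64_t)seed);
  const bool langevin = (thermo_kind == 1);
  double c1 = 1.0, c2 = 0.0;
  if (langevin) {
    if (damping <= 0.0) stop("damping must be positive");
    c1 = std::exp(-dt / damping);
    c2 = std::sqrt(T_target * (1.0 - c1 * c1));
  }

  // Verlet neighbor list with displacement-triggered rebuild
  const double skin = 0.4;
  std::vector<std::pair<int, int> > nlist;
  std::vector<char> has_excl(N, 0);
  for (int b = 0; b < bonds.nrow(); ++b) {
    has_excl[bonds(b, 0) - 1] = 1;
    has_excl[bonds(b, 1) - 1] = 1;
  }
  double travel = 0.0;
  auto rebuild = [&]() {
    nlist.clear();
    for_each_pair(px, py, pz, Lx, Ly, Lz, T.rcmax + skin, xshift,
      [&](int i, int j, double, double, double, double) {
        nlist.emplace_back(i, j);
      });
    travel = 0.0;
  };
  rebuild();
  double pe = compute_forces(px, py, pz, sp, Lx, Ly, Lz, T, topo, excl, xshift,
                             fx, fy, fz, vir, &nlist, &has_excl);

  auto wrap_particle = [&](int i) {
    // z-crossings carry the Lees-Edwards position/velocity offsets
    if (pz[i] >= Lz) { pz[i] -= Lz; px[i] -= xshift; vx[i] -= dvx_wrap; }
    else if (pz[i] < 0.0) { pz[i] += Lz; px[i] += xshift; vx[i] += dvx_wrap; }
    px[i] = wrap0L(px[i], Lx);
    py[i] = wrap0L(py[i], Ly);
    pz[i] = wrap0L(pz[i], Lz);
  };

  const double hdt = 0.5 * dt;
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < N; ++i) {       // B
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
    }
    for (int i = 0; i < N; ++i) {       // A (half)
      px[i] += hdt * vx[i]; py[i] += hdt * vy[i]; pz[i] += hdt * vz[i];
    }
    if (langevin) {                     // O
      for (int i = 0; i < N; ++i) {
        if (!thermo_transverse_only) vx[i] = c1 * vx[i] + c2 * gauss();
        vy[i] = c1 * vy[i] + c2 * gauss();
        vz[i] = c1 * vz[i] + c2 * gauss();
      }
    }
    for (int i = 0; i < N; ++i) {       // A (half)
      px[i] += hdt * vx[i]; py[i] += hdt * vy[i]; pz[i] += hdt * vz[i];
    }
    if (shear_rate != 0.0) {
      xshift += shear_rate * Lz * dt;
      xshift -= Lx * fast_round(xshift / Lx);
    }
    for (int i = 0; i < N; ++i) wrap_particle(i);
    // conservative travel bound: fastest particle plus boundary-image drift
    double v2max = 0.0;
    for (int i = 0; i < N; ++i) {
      double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > v2max) v2max = v2;
    }
    travel += (std::sqrt(v2max) + std::fabs(shear_rate) * Lz) * dt;
    if (2.0 * travel >= skin) rebuild();
    pe = compute_forces(px, py, pz, sp, Lx, Ly, Lz, T, topo, excl, xshift,
                        fx, fy, fz, vir, &nlist, &has_excl,
                        step == nsteps - 1);
    for (int i = 0; i < N; ++i) {       // B
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
    }
  }

  double ke = 0.0;
  for (int i = 0; i < N; ++i)
    ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  NumericMatrix P(N, 3), Vl(N, 3);
  for (int i = 0; i < N; ++i) {
    P(i, 0) = px[i]; P(i, 1) = py[i]; P(i, 2) = pz[i];
    Vl(i, 0) = vx[i]; Vl(i, 1) = vy[i]; Vl(i, 2) = vz[i];
  }
  NumericMatrix V(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) V(a, b) = vir[a * 3 + b];
  return List::create(_["pos"] = P, _["vel"] = Vl, _["xshift"] = xshift,
                      _["pe"] = pe, _["ke"] = ke, _["virial"] = V);
}
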