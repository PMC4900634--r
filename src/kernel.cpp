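#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unit system: A, ps, kcal/mol, e, amu.
// 1 kcal/mol = 418.4 amu*A^2/ps^2 (force -> acceleration conversion).
static const double KCAL_TO_ACC = 418.4;

// pairwise Coulomb + WCA interaction between atoms i and j; adds energy and
// the force on i (force on j is the negative). sigma chosen so the WCA term
// vanishes exactly at r = r_i + r_j.
static inline void pair_interaction(const double* xi, const double* xj,
                                    double qi, double qj, double ri, double rj,
                                    double kc, double eps,
                                    double* fi, double& e_coul, double& e_wca) {
  double dx = xi[0] - xj[0], dy = xi[1] - xj[1], dz = xi[2] - xj[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double qq = qi * qj;
  double rc = ri + rj;
  if (r2 < 1e-18) {
    if (qq != 0.0) stop("coincident charged atoms: Coulomb energy diverges");
    if (rc > 0.0) stop("coincident atoms with nonzero radii: repulsion diverges");
    return;
  }
  double r = std::sqrt(r2);
  if (qq != 0.0) {
    double e = kc * qq / r;
    e_coul += e;
    double fmag = e / r2; // kc*qq/r^3: scales the displacement vector
    fi[0] += fmag * dx;
    fi[1] += fmag * dy;
    fi[2] += fmag * dz;
  }
  if (rc > 0.0 && r < rc && eps > 0.0) {
    double sigma = rc / std::pow(2.0, 1.0 / 6.0);
    double sr2 = sigma * sigma / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    e_wca += 4.0 * eps * (sr12 - sr6) + eps;
    double fmag = 24.0 * eps * (2.0 * sr12 - sr6) / r2; // (dU/dr)/r with sign
    fi[0] += fmag * dx;
    fi[1] += fmag * dy;
    fi[2] += fmag * dz;
  }
}

// bonded-neighbor exclusions of the coarse model: pairs inside one small
// molecule (ligand bead cluster, lipid surrogate), within one residue, or
// in adjacent residues of the same protein chain do not interact
// (the 1-2/1-3 exclusion analog of molecular force fields)
static inline bool pair_excluded(int i, int j, const IntegerVector& mono,
                                 const IntegerVector& resno,
                                 const IntegerVector& molid,
                                 const LogicalVector& exclall) {
  if (molid[i] == molid[j]) {
    if (exclall[i]) return true;
    if (resno[i] == resno[j]) return true;
    if (mono[i] >= 0 && std::abs(resno[i] - resno[j]) <= 4) return true;
  }
  return false;
}

// Full energy/force evaluation over all pairs. eef is the field already
// converted to kcal/(mol*A*e); restraints are E = k*d^2.
// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix coords, NumericVector charge,
                       NumericVector radius, IntegerVector mono,
                       IntegerVector resno, IntegerVector molid,
                       LogicalVector exclall, NumericVector eef,
                       LogicalVector eef_mask, IntegerVector restr_atom,
                       NumericMatrix restr_ref, NumericVector restr_k,
                       double kc, double wca_eps) {
  int n = coords.nrow();
  NumericMatrix forces(n, 3);
  double e_coul = 0.0, e_wca = 0.0, e_restr = 0.0, e_eef = 0.0;
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = coords(i, 0); x[3 * i + 1] = coords(i, 1); x[3 * i + 2] = coords(i, 2);
  }
  double fi[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (pair_excluded(i, j, mono, resno, molid, exclall)) continue;
      fi[0] = fi[1] = fi[2] = 0.0;
      pair_interaction(&x[3 * i], &x[3 * j], charge[i], charge[j],
                       radius[i], radius[j], kc, wca_eps, fi, e_coul, e_wca);
      forces(i, 0) += fi[0]; forces(i, 1) += fi[1]; forces(i, 2) += fi[2];
      forces(j, 0) -= fi[0]; forces(j, 1) -= fi[1]; forces(j, 2) -= fi[2];
    }
  }
  for (int m = 0; m < restr_atom.size(); ++m) {
    int i = restr_atom[m];
    double k = restr_k[m];
    double d0 = x[3 * i] - restr_ref(m, 0);
    double d1 = x[3 * i + 1] - restr_ref(m, 1);
    double d2 = x[3 * i + 2] - restr_ref(m, 2);
    e_restr += k * (d0 * d0 + d1 * d1 + d2 * d2);
    forces(i, 0) -= 2.0 * k * d0;
    forces(i, 1) -= 2.0 * k * d1;
    forces(i, 2) -= 2.0 * k * d2;
  }
  for (int i = 0; i < n; ++i) {
    if (eef_mask[i]) {
      forces(i, 0) += charge[i] * eef[0];
      forces(i, 1) += charge[i] * eef[1];
      forces(i, 2) += charge[i] * eef[2];
      e_eef -= charge[i] * (eef[0] * x[3 * i] + eef[1] * x[3 * i + 1] +
                            eef[2] * x[3 * i + 2]);
    }
  }
  return List::create(_["coulomb"] = e_coul, _["wca"] = e_wca,
                      _["restraint"] = e_restr, _["eef"] = e_eef,
                      _["forces"] = forces);
}

struct DynState {
  std::vector<double> x;      // 3n coordinates
  int n;
};

// force on dynamic atoms only; intra-ligand pairs skipped (internal forces
// of a translation-only rigid cluster cancel on its centroid)
static void dyn_forces(const std::vector<double>& x, int n,
                       const NumericVector& charge, const NumericVector& radius,
                       const IntegerVector& mono, const IntegerVector& resno,
                       const IntegerVector& molid, const LogicalVector& exclall,
                       const NumericVector& eef, const LogicalVector& eef_mask,
                       const IntegerVector& restr_atom, const NumericMatrix& restr_ref,
                       const NumericVector& restr_k, double kc, double eps,
                       const std::vector<int>& dyn, const std::vector<char>& in_lig,
                       std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double e_c = 0.0, e_w = 0.0;
  double fi[3];
  for (size_t a = 0; a < dyn.size(); ++a) {
    int i = dyn[a];
    double* fa = &f[3 * a];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (in_lig[i] && in_lig[j]) continue;
      if (pair_excluded(i, j, mono, resno, molid, exclall)) continue;
      fi[0] = fi[1] = fi[2] = 0.0;
      pair_interaction(&x[3 * i], &x[3 * j], charge[i], charge[j],
                       radius[i], radius[j], kc, eps, fi, e_c, e_w);
      fa[0] += fi[0]; fa[1] += fi[1]; fa[2] += fi[2];
    }
    if (eef_mask[i]) {
      fa[0] += charge[i] * eef[0];
      fa[1] += charge[i] * eef[1];
      fa[2] += charge[i] * eef[2];
    }
  }
  for (int m = 0; m < restr_atom.size(); ++m) {
    int i = restr_atom[m];
    for (size_t a = 0; a < dyn.size(); ++a) {
      if (dyn[a] == i) {
        f[3 * a]     -= 2.0 * restr_k[m] * (x[3 * i]     - restr_ref(m, 0));
        f[3 * a + 1] -= 2.0 * restr_k[m] * (x[3 * i + 1] - restr_ref(m, 1));
        f[3 * a + 2] -= 2.0 * restr_k[m] * (x[3 * i + 2] - restr_ref(m, 2));
        break;
      }
    }
  }
}

// BAOAB Langevin integrator. mobile: 0-based indices of free atoms;
// lig: 0-based indices of rigid (translation-only) ligand beads.
// Gaussian noise is drawn from R's RNG, so trajectories are reproducible
// given set.seed() on the R side.
// [[Rcpp::export]]
List baoab_cpp(NumericMatrix coords, NumericVector charge, NumericVector radius,
               IntegerVector mono, IntegerVector resno, IntegerVector molid,
               LogicalVector exclall,
               NumericVector mass, NumericVector eef, LogicalVector eef_mask,
               IntegerVector restr_atom, NumericMatrix restr_ref,
               NumericVector restr_k, double kc, double wca_eps,
               IntegerVector mobile, IntegerVector lig,
               double dt, double gamma, double kBT,
               int n_steps, int save_every) {
  int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  std::vector<char> in_lig(n, 0);
  for (int k = 0; k < lig.size(); ++k) in_lig[lig[k]] = 1;

  // dynamic entity list: each free mobile atom, then (if present) the ligand
  // centroid as one pseudo-particle. dyn holds a representative atom index
  // per entity for the force loop (ligand handled separately below).
  std::vector<int> dyn;
  for (int k = 0; k < mobile.size(); ++k) dyn.push_back(mobile[k]);
  for (int k = 0; k < lig.size(); ++k) dyn.push_back(lig[k]);
  size_t n_free = mobile.size();
  size_t n_dyn = dyn.size();
  if (n_dyn == 0) stop("no mobile atoms");

  // ligand centroid and fixed offsets
  bool has_lig = lig.size() > 0;
  double lig_com[3] = {0, 0, 0};
  double lig_mass = 0.0;
  std::vector<double> lig_off(3 * lig.size());
  if (has_lig) {
    for (int k = 0; k < lig.size(); ++k) {
      for (int d = 0; d < 3; ++d) lig_com[d] += x[3 * lig[k] + d];
      lig_mass += mass[lig[k]];
    }
    for (int d = 0; d < 3; ++d) lig_com[d] /= lig.size();
    for (int k = 0; k < lig.size(); ++k)
      for (int d = 0; d < 3; ++d)
        lig_off[3 * k + d] = x[3 * lig[k] + d] - lig_com[d];
  }

  // velocities: one 3-vector per free atom + one for the ligand
  size_t n_ent = n_free + (has_lig ? 1 : 0);
  std::vector<double> v(3 * n_ent, 0.0), fent(3 * n_ent, 0.0);
  std::vector<double> fdyn(3 * n_dyn, 0.0);
  std::vector<double> ent_mass(n_ent);
  for (size_t a = 0; a < n_free; ++a) ent_mass[a] = mass[mobile[a]];
  if (has_lig) ent_mass[n_free] = lig_mass;

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  auto gather_forces = [&]() {
    dyn_forces(x, n, charge, radius, mono, resno, molid, exclall,
               eef, eef_mask, restr_atom, restr_ref,
               restr_k, kc, wca_eps, dyn, in_lig, fdyn);
    for (size_t a = 0; a < n_free; ++a)
      for (int d = 0; d < 3; ++d) fent[3 * a + d] = fdyn[3 * a + d];
    if (has_lig) {
      for (int d = 0; d < 3; ++d) fent[3 * n_free + d] = 0.0;
      for (int k = 0; k < lig.size(); ++k)
        for (int d = 0; d < 3; ++d)
          fent[3 * n_free + d] += fdyn[3 * (n_free + k) + d];
    }
  };
  auto apply_positions = [&](double h) {
    for (size_t a = 0; a < n_free; ++a) {
      int i = mobile[a];
      for (int d = 0; d < 3; ++d) x[3 * i + d] += h * v[3 * a + d];
    }
    if (has_lig) {
      for (int d = 0; d < 3; ++d) lig_com[d] += h * v[3 * n_free + d];
      for (int k = 0; k < lig.size(); ++k)
        for (int d = 0; d < 3; ++d)
          x[3 * lig[k] + d] = lig_com[d] + lig_off[3 * k + d];
    }
  };

  int n_frames = n_steps / save_every + 1;
  NumericVector frames(Dimension(n_frames, n, 3));
  auto save_frame = [&](int slot) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[slot + n_frames * (i + n * d)] = x[3 * i + d];
  };
  save_frame(0);
  int saved = 1;

  gather_forces();
  RNGScope rng;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (size_t a = 0; a < n_ent; ++a) {
      double inv_m = KCAL_TO_ACC / ent_mass[a];
      for (int d = 0; d < 3; ++d)
        v[3 * a + d] += 0.5 * dt * fent[3 * a + d] * inv_m;
    }
    apply_positions(0.5 * dt); // A
    // O: Ornstein-Uhlenbeck
    for (size_t a = 0; a < n_ent; ++a) {
      double sigma_v = std::sqrt(kBT * KCAL_TO_ACC / ent_mass[a]);
      for (int d = 0; d < 3; ++d)
        v[3 * a + d] = c1 * v[3 * a + d] + c2 * sigma_v * R::norm_rand();
    }
    apply_positions(0.5 * dt); // A
    gather_forces();
    for (size_t a = 0; a < n_ent; ++a) { // B
      double inv_m = KCAL_TO_ACC / ent_mass[a];
      for (int d = 0; d < 3; ++d)
        v[3 * a + d] += 0.5 * dt * fent[3 * a + d] * inv_m;
    }
    for (size_t a = 0; a < n_ent; ++a)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(v[3 * a + d]))
          stop("dynamics diverged at step %d (non-finite velocity)", step);
    if (step % save_every == 0) { save_frame(saved); ++saved; }
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_coords(i, d) = x[3 * i + d];
  return List::create(_["frames"] = frames, _["n_frames"] = saved,
                      _["final"] = final_coords);
}

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// node dielectric map: eps_w outside, eps_m in the slab, eps_in inside any
// solute sphere (overrides the slab)
// [[Rcpp::export]]
NumericVector eps_node_map_cpp(IntegerVector dims, NumericVector origin,
                               double h, NumericMatrix coords,
                               NumericVector radius, double eps_in,
                               double eps_m, double eps_w, double z_lo,
                               double z_hi) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector eps(nx * ny * nz);
  bool has_slab = z_hi > z_lo;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * h;
    double val = (has_slab && z >= z_lo && z <= z_hi) ? eps_m : eps_w;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        eps[idx3(i, j, k, nx, ny)] = val;
  }
  int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    double r = radius[a];
    if (r <= 0) continue;
    double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    int i0 = std::max(0, (int)std::ceil((cx - r - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((cx + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((cy - r - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((cy + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((cz - r - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((cz + r - origin[2]) / h));
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - cy;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - cx;
          if (dx * dx + dy * dy + dz * dz <= r2)
            eps[idx3(i, j, k, nx, ny)] = eps_in;
        }
      }
    }
  }
  return eps;
}

// analytic single-dielectric Coulomb potential on the six grid faces
// (Dirichlet boundary condition)
// [[Rcpp::export]]
NumericVector boundary_phi_cpp(IntegerVector dims, NumericVector origin,
                               double h, NumericMatrix coords,
                               NumericVector charge, double kc,
                               double eps_ref) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi(nx * ny * nz);
  int na = coords.nrow();
  auto set_node = [&](int i, int j, int k) {
    double px = origin[0] + i * h, py = origin[1] + j * h, pz = origin[2] + k * h;
    double s = 0.0;
    for (int a = 0; a < na; ++a) {
      if (charge[a] == 0.0) continue;
      double dx = px - coords(a, 0), dy = py - coords(a, 1), dz = pz - coords(a, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      s += kc * charge[a] / (eps_ref * r);
    }
    phi[idx3(i, j, k, nx, ny)] = s;
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { set_node(i, j, 0); set_node(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { set_node(i, 0, k); set_node(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { set_node(0, j, k); set_node(nx - 1, j, k); }
  return phi;
}

// 7-point finite-difference Poisson solve with harmonic-mean edge
// dielectrics and Jacobi-preconditioned conjugate gradients.
// b_interior = 4*pi*kc*q_node/h; phi0 carries the Dirichlet boundary values.
// [[Rcpp::export]]
List pb_solve_cpp(IntegerVector dims, NumericVector eps, NumericVector b,
                  NumericVector phi0, double tol, int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<double> wx((nx - 1) * ny * nz), wy(nx * (ny - 1) * nz),
      wz(nx * ny * (nz - 1));
  auto hm = [](double a, double b2) { return 2.0 * a * b2 / (a + b2); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i)
        wx[i + (nx - 1) * (j + ny * k)] =
            hm(eps[idx3(i, j, k, nx, ny)], eps[idx3(i + 1, j, k, nx, ny)]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i)
        wy[i + nx * (j + (ny - 1) * k)] =
            hm(eps[idx3(i, j, k, nx, ny)], eps[idx3(i, j + 1, k, nx, ny)]);
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        wz[i + nx * (j + ny * k)] =
            hm(eps[idx3(i, j, k, nx, ny)], eps[idx3(i, j, k + 1, nx, ny)]);

  auto interior = [&](int i, int j, int k) {
    return i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1;
  };

  // effective RHS: source + boundary contributions; diagonal for Jacobi
  std::vector<double> rhs(n, 0.0), diag(n, 1.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        int p = idx3(i, j, k, nx, ny);
        double wxm = wx[(i - 1) + (nx - 1) * (j + ny * k)];
        double wxp = wx[i + (nx - 1) * (j + ny * k)];
        double wym = wy[i + nx * ((j - 1) + (ny - 1) * k)];
        double wyp = wy[i + nx * (j + (ny - 1) * k)];
        double wzm = wz[i + nx * (j + ny * (k - 1))];
        double wzp = wz[i + nx * (j + ny * k)];
        diag[p] = wxm + wxp + wym + wyp + wzm + wzp;
        double bb = b[p];
        if (!interior(i - 1, j, k)) bb += wxm * phi0[idx3(i - 1, j, k, nx, ny)];
        if (!interior(i + 1, j, k)) bb += wxp * phi0[idx3(i + 1, j, k, nx, ny)];
        if (!interior(i, j - 1, k)) bb += wym * phi0[idx3(i, j - 1, k, nx, ny)];
        if (!interior(i, j + 1, k)) bb += wyp * phi0[idx3(i, j + 1, k, nx, ny)];
        if (!interior(i, j, k - 1)) bb += wzm * phi0[idx3(i, j, k - 1, nx, ny)];
        if (!interior(i, j, k + 1)) bb += wzp * phi0[idx3(i, j, k + 1, nx, ny)];
        rhs[p] = bb;
      }

  auto matvec = [&](const std::vector<double>& xv, std::vector<double>& out) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          int p = idx3(i, j, k, nx, ny);
          double acc = diag[p] * xv[p];
          acc -= wx[(i - 1) + (nx - 1) * (j + ny * k)] * xv[p - 1];
          acc -= wx[i + (nx - 1) * (j + ny * k)] * xv[p + 1];
          acc -= wy[i + nx * ((j - 1) + (ny - 1) * k)] * xv[p - nx];
          acc -= wy[i + nx * (j + (ny - 1) * k)] * xv[p + nx];
          acc -= wz[i + nx * (j + ny * (k - 1))] * xv[p - nx * ny];
          acc -= wz[i + nx * (j + ny * k)] * xv[p + nx * ny];
          out[p] = acc;
        }
  };

  std::vector<double> xv(n, 0.0), r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);
  double bnorm = 0.0;
  for (int q = 0; q < n; ++q) { r[q] = rhs[q]; bnorm += rhs[q] * rhs[q]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  for (int q = 0; q < n; ++q) z[q] = r[q] / diag[q];
  p = z;
  double rz = 0.0;
  for (int q = 0; q < n; ++q) rz += r[q] * z[q];
  std::vector<double> history;
  double resid = 1.0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    matvec(p, Ap);
    double pAp = 0.0;
    for (int q = 0; q < n; ++q) pAp += p[q] * Ap[q];
    if (pAp == 0.0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int q = 0; q < n; ++q) {
      xv[q] += alpha * p[q];
      r[q] -= alpha * Ap[q];
      rnorm += r[q] * r[q];
    }
    resid = std::sqrt(rnorm) / bnorm;
    history.push_back(resid);
    if (resid < tol) { ++it; break; }
    double rz_new = 0.0;
    for (int q = 0; q < n; ++q) {
      z[q] = r[q] / diag[q];
      rz_new += r[q] * z[q];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int q = 0; q < n; ++q) p[q] = z[q] + beta * p[q];
  }
  // full potential: interior solution + boundary values
  NumericVector phi(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int q = idx3(i, j, k, nx, ny);
        phi[q] = interior(i, j, k) ? xv[q] : phi0[q];
      }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = resid, _["history"] = wrap(history),
                      _["converged"] = resid < tol);
}
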