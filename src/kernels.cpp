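// Inner loops of the surrogate docker, clash scoring, and strain-energy
// relaxation. Everything here is plain pairwise geometry; the science-level
// choices (potentials, parameters) are documented on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// soft 6-12 van der Waals with decoupled attraction and repulsion
// scales: the attractive branch (r >= r0) is scaled by eps, the
// repulsive branch by rep_eps (continuous at r0, where the energy is
// -eps), and below soft_frac * r0 the repulsion continues linearly so
// interpenetrating poses stay finite and sortable
static inline double soft_lj(double r, double r0, double eps,
                             double rep_eps, double soft_frac) {
  if (r >= r0) {
    double q = r0 / r;
    double q6 = q * q * q; q6 *= q6;
    return eps * (q6 * q6 - 2.0 * q6);
  }
  double rs = soft_frac * r0;
  if (r >= rs) {
    double q = r0 / r;
    double q6 = q * q * q; q6 *= q6;
    return -eps + rep_eps * (q6 * q6 - 2.0 * q6 + 1.0);
  }
  double q = r0 / rs;
  double q6 = q * q * q; q6 *= q6;
  double e_rs = -eps + rep_eps * (q6 * q6 - 2.0 * q6 + 1.0);
  double de_rs = rep_eps * (-12.0 * (q6 * q6) + 12.0 * q6) / rs;
  return e_rs + de_rs * (r - rs);
}

// interaction energy of one rigid ligand pose against the receptor:
// soft 6-12 over all pairs plus a gaussian distance-damped attraction
// between polar (N/O) atom pairs
// [[Rcpp::export]]
double cpp_pose_energy(NumericMatrix lig, NumericVector lig_rad,
                       LogicalVector lig_polar, NumericMatrix prot,
                       NumericVector prot_rad, LogicalVector prot_polar,
                       double eps, double rep_eps, double polar_eps,
                       double polar_r0, double polar_sigma,
                       double soft_frac, double cutoff) {
  const int nl = lig.nrow(), np = prot.nrow();
  const double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < nl; ++i) {
    const double xi = lig(i, 0), yi = lig(i, 1), zi = lig(i, 2);
    for (int j = 0; j < np; ++j) {
      const double dx = xi - prot(j, 0), dy = yi - prot(j, 1),
                   dz = zi - prot(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      const double r = std::sqrt(r2);
      const double r0 = lig_rad[i] + prot_rad[j];
      e += soft_lj(r, r0, eps, rep_eps, soft_frac);
      if (lig_polar[i] && prot_polar[j]) {
        const double d = (r - polar_r0) / polar_sigma;
        e -= polar_eps * std::exp(-0.5 * d * d);
      }
    }
  }
  return e;
}

// exhaustive rigid scan: every orientation x every translation grid point,
// restricted to grid points in the receptor's contact shell; returns the
// top_k best (energy, orientation index, tx, ty, tz) rows sorted by energy
// [[Rcpp::export]]
NumericMatrix cpp_dock_scan(NumericMatrix prot, NumericVector prot_rad,
                            LogicalVector prot_polar, NumericMatrix lig0,
                            NumericVector lig_rad, LogicalVector lig_polar,
                            NumericMatrix rots, NumericVector grid_min,
                            IntegerVector grid_dim, double spacing,
                            double eps, double rep_eps, double polar_eps,
                            double polar_r0, double polar_sigma,
                            double soft_frac, double cutoff, int top_k) {
  const int np = prot.nrow(), nl = lig0.nrow(), nrot = rots.nrow() / 3;
  // ligand radius about its centroid (lig0 is pre-centered)
  double lig_reach = 0.0;
  for (int i = 0; i < nl; ++i) {
    double d = std::sqrt(lig0(i, 0) * lig0(i, 0) + lig0(i, 1) * lig0(i, 1) +
                         lig0(i, 2) * lig0(i, 2));
    lig_reach = std::max(lig_reach, d);
  }
  const double shell_far = cutoff + lig_reach;
  const double shell_near = 1.0; // centers buried this deep are hopeless
  // rotated ligand copies
  std::vector<std::vector<double>> rlig(nrot,
                                        std::vector<double>(3 * nl));
  for (int k = 0; k < nrot; ++k) {
    for (int i = 0; i < nl; ++i) {
      for (int a = 0; a < 3; ++a) {
        rlig[k][3 * i + a] = rots(3 * k + a, 0) * lig0(i, 0) +
                             rots(3 * k + a, 1) * lig0(i, 1) +
                             rots(3 * k + a, 2) * lig0(i, 2);
      }
    }
  }
  struct Pose { double e; int rot; double t[3]; };
  std::vector<Pose> best;
  double worst_kept = R_PosInf;
  const int nx = grid_dim[0], ny = grid_dim[1], nz = grid_dim[2];
  const double cut2 = cutoff * cutoff;
  for (int ix = 0; ix < nx; ++ix) {
    const double tx = grid_min[0] + ix * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      const double ty = grid_min[1] + iy * spacing;
      for (int iz = 0; iz < nz; ++iz) {
        const double tz = grid_min[2] + iz * spacing;
        // nearest receptor atom to this center
        double dmin2 = R_PosInf;
        for (int j = 0; j < np; ++j) {
          const double dx = tx - prot(j, 0), dy = ty - prot(j, 1),
                       dz = tz - prot(j, 2);
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < dmin2) dmin2 = r2;
        }
        const double dmin = std::sqrt(dmin2);
        if (dmin > shell_far || dmin < shell_near) continue;
        for (int k = 0; k < nrot; ++k) {
          double e = 0.0;
          const std::vector<double>& L = rlig[k];
          for (int i = 0; i < nl; ++i) {
            const double xi = L[3 * i] + tx, yi = L[3 * i + 1] + ty,
                         zi = L[3 * i + 2] + tz;
            for (int j = 0; j < np; ++j) {
              const double dx = xi - prot(j, 0), dy = yi - prot(j, 1),
                           dz = zi - prot(j, 2);
              const double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 > cut2) continue;
              const double r = std::sqrt(r2);
              const double r0 = lig_rad[i] + prot_rad[j];
              e += soft_lj(r, r0, eps, rep_eps, soft_frac);
              if (lig_polar[i] && prot_polar[j]) {
                const double d = (r - polar_r0) / polar_sigma;
                e -= polar_eps * std::exp(-0.5 * d * d);
              }
            }
          }
          if ((int)best.size() < top_k || e < worst_kept) {
            Pose p; p.e = e; p.rot = k; p.t[0] = tx; p.t[1] = ty; p.t[2] = tz;
            best.push_back(p);
            std::sort(best.begin(), best.end(),
                      [](const Pose& a, const Pose& b) { return a.e < b.e; });
            if ((int)best.size() > top_k) best.pop_back();
            worst_kept = best.back().e;
          }
        }
      }
    }
  }
  NumericMatrix out(best.size(), 5);
  for (size_t i = 0; i < best.size(); ++i) {
    out(i, 0) = best[i].e;
    out(i, 1) = best[i].rot + 1; // 1-based for R
    out(i, 2) = best[i].t[0];
    out(i, 3) = best[i].t[1];
    out(i, 4) = best[i].t[2];
  }
  return out;
}

// quadratic overlap clash penalty within one atom set, excluding pairs
// closer than min_seq_sep in residue numbering (bonded neighbourhood)
// [[Rcpp::export]]
double cpp_clash_energy(NumericMatrix xyz, NumericVector rad,
                        IntegerVector resno, double k, int min_seq_sep) {
  const int n = xyz.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(resno[i] - resno[j]) < min_seq_sep) continue;
      const double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
                   dz = xyz(i, 2) - xyz(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r0 = rad[i] + rad[j];
      if (r2 < r0 * r0) {
        const double ov = r0 - std::sqrt(r2);
        e += k * ov * ov;
      }
    }
  }
  return e;
}

// clash penalty between two atom sets (e.g. protein vs ligand)
// [[Rcpp::export]]
double cpp_clash_cross(NumericMatrix a, NumericVector rad_a, NumericMatrix b,
                       NumericVector rad_b, double k) {
  double e = 0.0;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
                   dz = a(i, 2) - b(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r0 = rad_a[i] + rad_b[j];
      if (r2 < r0 * r0) {
        const double ov = r0 - std::sqrt(r2);
        e += k * ov * ov;
      }
    }
  }
  return e;
}

// per-residue capped contact count over C-alpha coordinates: each residue
// contributes min(#neighbours in [lo, hi], cap); returns the sum
// [[Rcpp::export]]
double cpp_contact_count(NumericMatrix ca, double lo, double hi, int cap) {
  const int n = ca.nrow();
  std::vector<int> cnt(n, 0);
  const double lo2 = lo * lo, hi2 = hi * hi;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = ca(i, 0) - ca(j, 0), dy = ca(i, 1) - ca(j, 1),
                   dz = ca(i, 2) - ca(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= lo2 && r2 <= hi2) { ++cnt[i]; ++cnt[j]; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::min(cnt[i], cap);
  return s;
}

// strain energy and gradient of the relaxation surrogate:
//   bonds:  k_b * (|r_i - r_j| - r0)^2 over consecutive backbone pairs
//   angles: k_a * (theta - theta0)^2 over C-alpha pseudo-angle triplets
//   clash:  quadratic overlap within the protein and protein-vs-ligand
// xyz holds protein atoms then ligand atoms (n_prot + n_lig rows); the
// gradient is returned for all atoms (the R driver keeps the ligand rigid)
// [[Rcpp::export]]
List cpp_strain_grad(NumericMatrix xyz, int n_prot, IntegerMatrix bonds,
                     NumericVector bond_r0, double bond_k,
                     IntegerMatrix angles, NumericVector angle_t0,
                     double angle_k, NumericVector rad, IntegerVector resno,
                     double clash_k, int min_seq_sep) {
  const int n = xyz.nrow();
  NumericMatrix grad(n, 3);
  double e = 0.0;
  // bonds (indices are 0-based rows of xyz)
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0), j = bonds(b, 1);
    double d[3];
    double r2 = 0.0;
    for (int a = 0; a < 3; ++a) { d[a] = xyz(i, a) - xyz(j, a); r2 += d[a] * d[a]; }
    const double r = std::sqrt(r2);
    const double dev = r - bond_r0[b];
    e += bond_k * dev * dev;
    const double f = 2.0 * bond_k * dev / std::max(r, 1e-12);
    for (int a = 0; a < 3; ++a) {
      grad(i, a) += f * d[a];
      grad(j, a) -= f * d[a];
    }
  }
  // pseudo-angles
  for (int t = 0; t < angles.nrow(); ++t) {
    const int i = angles(t, 0), j = angles(t, 1), k2 = angles(t, 2);
    double u[3], v[3];
    double nu = 0.0, nv = 0.0, uv = 0.0;
    for (int a = 0; a < 3; ++a) {
      u[a] = xyz(i, a) - xyz(j, a);
      v[a] = xyz(k2, a) - xyz(j, a);
      nu += u[a] * u[a]; nv += v[a] * v[a]; uv += u[a] * v[a];
    }
    nu = std::sqrt(nu); nv = std::sqrt(nv);
    double ct = uv / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    const double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    const double th = std::acos(ct);
    const double dev = th - angle_t0[t];
    e += angle_k * dev * dev;
    const double pref = 2.0 * angle_k * dev;
    for (int a = 0; a < 3; ++a) {
      const double dthi = (ct * u[a] / nu - v[a] / nv) / (nu * st);
      const double dthk = (ct * v[a] / nv - u[a] / nu) / (nv * st);
      grad(i, a) += pref * dthi;
      grad(k2, a) += pref * dthk;
      grad(j, a) -= pref * (dthi + dthk);
    }
  }
  // clashes: within protein (sequence-separated), and protein vs ligand
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const bool both_prot = (i < n_prot) && (j < n_prot);
      const bool cross = (i < n_prot) != (j < n_prot);
      if (both_prot) {
        if (std::abs(resno[i] - resno[j]) < min_seq_sep) continue;
      } else if (!cross) {
        continue; // ligand-internal geometry is rigid, owned by the docker
      }
      double d[3];
      double r2 = 0.0;
      for (int a = 0; a < 3; ++a) { d[a] = xyz(i, a) - xyz(j, a); r2 += d[a] * d[a]; }
      const double r0 = rad[i] + rad[j];
      if (r2 >= r0 * r0) continue;
      const double r = std::sqrt(std::max(r2, 1e-12));
      const double ov = r0 - r;
      e += clash_k * ov * ov;
      const double f = -2.0 * clash_k * ov / std::max(r, 1e-6);
      for (int a = 0; a < 3; ++a) {
        grad(i, a) += f * d[a];
        grad(j, a) -= f * d[a];
      }
    }
  }
  return List::create(_["energy"] = e, _["grad"] = grad);
}
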