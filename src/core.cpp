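// Coarse-grained energy and Monte Carlo move kernel.
//
// The energy is a documented stand-in with three blocks:
//   intra-peptide: flat-bottom pseudo-bond-angle band, secondary-structure
//                  angle bias, excluded volume between nonconsecutive Calphas
//   inter-chain:   residue-type contact potential on side-chain centroids in
//                  a distance shell, Calpha-Calpha soft-core clash, positive
//                  penalty for contacts with excluded ("unlikely to bind")
//                  receptor residues
//   restraints:    flat-bottom linear penalties on receptor Calpha pairs
// All indices arriving from R are 1-based and converted here.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct EnergyParams {
  double contact_lo, contact_hi;   // sc-sc contact shell (A)
  double clash_distance, k_clash;  // soft-core excluded volume
  double peptide_min_sep;          // intra-peptide Calpha minimum separation
  double ss_bias;                  // angle bias strength (per rad^2)
  double exclusion_penalty;        // per contact with an excluded residue
  double angle_lo, angle_hi;       // allowed pseudo-bond-angle band (rad)
  double k_angle;                  // band-violation stiffness (per rad^2)
  double helix_angle, strand_angle; // SS target angles (rad)
};

static EnergyParams read_params(const List& par) {
  EnergyParams p;
  p.contact_lo = par["contact_lo"];
  p.contact_hi = par["contact_hi"];
  p.clash_distance = par["clash_distance"];
  p.k_clash = par["k_clash"];
  p.peptide_min_sep = par["peptide_min_sep"];
  p.ss_bias = par["ss_bias"];
  p.exclusion_penalty = par["exclusion_penalty"];
  p.angle_lo = par["angle_lo"];
  p.angle_hi = par["angle_hi"];
  p.k_angle = par["k_angle"];
  p.helix_angle = par["helix_angle"];
  p.strand_angle = par["strand_angle"];
  return p;
}

static inline double dist3(const NumericMatrix& a, int i,
                           const NumericMatrix& b, int j) {
  double dx = a(i, 0) - b(j, 0);
  double dy = a(i, 1) - b(j, 1);
  double dz = a(i, 2) - b(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// pseudo-bond angle at residue i of ca (0-based), radians
static double bond_angle(const NumericMatrix& ca, int i) {
  double u[3], v[3];
  double nu = 0, nv = 0, dot = 0;
  for (int k = 0; k < 3; ++k) {
    u[k] = ca(i - 1, k) - ca(i, k);
    v[k] = ca(i + 1, k) - ca(i, k);
    nu += u[k] * u[k];
    nv += v[k] * v[k];
    dot += u[k] * v[k];
  }
  double c = dot / std::sqrt(nu * nv);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c);
}

// total/binding/restraint energy of one pose
static NumericVector energy_impl(const NumericMatrix& ca_r,
                                 const NumericMatrix& sc_r,
                                 const NumericMatrix& ca_p,
                                 const NumericMatrix& sc_p,
                                 const IntegerVector& type_r,
                                 const IntegerVector& type_p,
                                 const NumericMatrix& cmat,
                                 const IntegerVector& rest_i,
                                 const IntegerVector& rest_j,
                                 const NumericVector& rest_d,
                                 const NumericVector& rest_tol,
                                 const NumericVector& rest_slope,
                                 const LogicalVector& excluded,
                                 const IntegerVector& ss_p,
                                 const EnergyParams& p) {
  const int nr = ca_r.nrow(), np = ca_p.nrow();

  double e_intra = 0.0;
  for (int i = 1; i + 1 < np; ++i) {
    double th = bond_angle(ca_p, i);
    if (th < p.angle_lo) e_intra += p.k_angle * (p.angle_lo - th) * (p.angle_lo - th);
    if (th > p.angle_hi) e_intra += p.k_angle * (th - p.angle_hi) * (th - p.angle_hi);
    int s = ss_p[i];
    if (s == 1) e_intra += p.ss_bias * (th - p.helix_angle) * (th - p.helix_angle);
    else if (s == 2) e_intra += p.ss_bias * (th - p.strand_angle) * (th - p.strand_angle);
  }
  for (int i = 0; i < np; ++i) {
    for (int j = i + 2; j < np; ++j) {
      double d = dist3(ca_p, i, ca_p, j);
      if (d < p.peptide_min_sep) {
        double v = p.peptide_min_sep - d;
        e_intra += p.k_clash * v * v;
      }
    }
  }

  // Inter-chain terms. The attractive contact energy saturates: each
  // peptide residue contributes only its single most favorable in-shell
  // contact (a side chain packs against one partner), while unfavorable
  // contacts and exclusion penalties are summed over all in-shell pairs.
  double e_inter = 0.0;
  for (int ip = 0; ip < np; ++ip) {
    double best = 0.0;
    for (int ir = 0; ir < nr; ++ir) {
      double dca = dist3(ca_p, ip, ca_r, ir);
      if (dca < p.clash_distance) {
        double v = p.clash_distance - dca;
        e_inter += p.k_clash * v * v;
      }
      if (dca < p.contact_hi + 12.0) {  // sc-sc can't reach beyond this
        double dsc = dist3(sc_p, ip, sc_r, ir);
        if (dsc >= p.contact_lo && dsc <= p.contact_hi) {
          double e = cmat(type_p[ip] - 1, type_r[ir] - 1);
          if (e < best) best = e; else if (e > 0) e_inter += e;
          if (excluded[ir]) e_inter += p.exclusion_penalty;
        }
      }
    }
    e_inter += best;
  }

  double e_rest = 0.0;
  const int nrest = rest_i.size();
  for (int k = 0; k < nrest; ++k) {
    double d = dist3(ca_r, rest_i[k] - 1, ca_r, rest_j[k] - 1);
    double viol = std::fabs(d - rest_d[k]) - rest_tol[k];
    if (viol > 0) e_rest += rest_slope[k] * viol;
  }

  return NumericVector::create(_["total"] = e_intra + e_inter + e_rest,
                               _["binding"] = e_inter,
                               _["restraint"] = e_rest,
                               _["intra"] = e_intra);
}

// [[Rcpp::export(name = ".cpp_energy")]]
NumericVector cpp_energy(NumericMatrix ca_r, NumericMatrix sc_r,
                         NumericMatrix ca_p, NumericMatrix sc_p,
                         IntegerVector type_r, IntegerVector type_p,
                         NumericMatrix cmat,
                         IntegerVector rest_i, IntegerVector rest_j,
                         NumericVector rest_d, NumericVector rest_tol,
                         NumericVector rest_slope,
                         LogicalVector excluded, IntegerVector ss_p,
                         List par) {
  return energy_impl(ca_r, sc_r, ca_p, sc_p, type_r, type_p, cmat,
                     rest_i, rest_j, rest_d, rest_tol, rest_slope,
                     excluded, ss_p, read_params(par));
}

// uniform point in a ball of radius r
static void ball_sample(double r, double* out) {
  double v[3];
  double n2 = 0;
  for (int k = 0; k < 3; ++k) { v[k] = norm_rand(); n2 += v[k] * v[k]; }
  double n = std::sqrt(n2);
  double rad = r * std::cbrt(unif_rand());
  for (int k = 0; k < 3; ++k) out[k] = rad * v[k] / n;
}

// Rodrigues rotation of point x about unit axis u through origin
static void rotate_point(const double* u, double s, double c, double* x) {
  double ux = u[1] * x[2] - u[2] * x[1];
  double uy = u[2] * x[0] - u[0] * x[2];
  double uz = u[0] * x[1] - u[1] * x[0];
  double dot = u[0] * x[0] + u[1] * x[1] + u[2] * x[2];
  double y[3];
  for (int k = 0; k < 3; ++k) {
    double cross = (k == 0) ? ux : (k == 1) ? uy : uz;
    y[k] = x[k] * c + cross * s + u[k] * dot * (1 - c);
  }
  for (int k = 0; k < 3; ++k) x[k] = y[k];
}

// canonical peptide side-chain placement: a deterministic, covariant
// function of the Calpha trace (mirrors the R rule in .sc_direction)
static void unit3(double* v) {
  double n = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  for (int k = 0; k < 3; ++k) v[k] /= n;
}

static void perp3(const double* v, double* out) {
  int m = 0;
  if (std::fabs(v[1]) < std::fabs(v[m])) m = 1;
  if (std::fabs(v[2]) < std::fabs(v[m])) m = 2;
  double e[3] = {0, 0, 0};
  e[m] = 1;
  out[0] = v[1]*e[2] - v[2]*e[1];
  out[1] = v[2]*e[0] - v[0]*e[2];
  out[2] = v[0]*e[1] - v[1]*e[0];
  unit3(out);
}

static void canon_sc(const NumericMatrix& ca, const NumericVector& scd,
                     NumericMatrix& sc) {
  const int n = ca.nrow();
  for (int i = 0; i < n; ++i) {
    if (scd[i] == 0.0) {  // glycine: centroid on the Calpha
      for (int k = 0; k < 3; ++k) sc(i, k) = ca(i, k);
      continue;
    }
    if (n == 1) {  // no chain direction: fixed axis (documented edge case)
      for (int k = 0; k < 3; ++k) sc(i, k) = ca(i, k) + (k == 2 ? scd[i] : 0.0);
      continue;
    }
    double u[3], w[3], b[3];
    if (i > 0 && i + 1 < n) {
      for (int k = 0; k < 3; ++k) u[k] = ca(i - 1, k) - ca(i, k);
      for (int k = 0; k < 3; ++k) w[k] = ca(i + 1, k) - ca(i, k);
    } else if (i == 0) {
      for (int k = 0; k < 3; ++k) u[k] = ca(1, k) - ca(0, k);
      if (n == 2) {
        unit3(u);
        for (int k = 0; k < 3; ++k) sc(i, k) = ca(i, k) - scd[i] * u[k];
        continue;
      }
      for (int k = 0; k < 3; ++k) w[k] = ca(2, k) - ca(1, k);
    } else {
      for (int k = 0; k < 3; ++k) u[k] = ca(n - 2, k) - ca(n - 1, k);
      if (n == 2) {
        unit3(u);
        for (int k = 0; k < 3; ++k) sc(i, k) = ca(i, k) - scd[i] * u[k];
        continue;
      }
      for (int k = 0; k < 3; ++k) w[k] = ca(n - 3, k) - ca(n - 2, k);
    }
    unit3(u); unit3(w);
    for (int k = 0; k < 3; ++k) b[k] = u[k] + w[k];
    double nb = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
    double dir[3];
    if (nb < 1e-8) {
      perp3(u, dir);
    } else {
      for (int k = 0; k < 3; ++k) dir[k] = -b[k] / nb;
    }
    for (int k = 0; k < 3; ++k) sc(i, k) = ca(i, k) + scd[i] * dir[k];
  }
}

static bool bonds_ok(const NumericMatrix& ca, const IntegerVector& chain_idx,
                     int i, double lo, double hi) {
  int n = ca.nrow();
  if (i > 0 && chain_idx[i - 1] == chain_idx[i]) {
    double d = dist3(ca, i - 1, ca, i);
    if (d < lo || d > hi) return false;
  }
  if (i + 1 < n && chain_idx[i + 1] == chain_idx[i]) {
    double d = dist3(ca, i, ca, i + 1);
    if (d < lo || d > hi) return false;
  }
  return true;
}

// Run n_moves Metropolis moves at temperature T; full energy re-evaluation
// per proposal (systems are small). Move mix: peptide single-residue
// displacement, 2-4 residue crankshaft, rigid-body peptide move, receptor
// single-Calpha displacement. Returns updated coordinates, the energy of the
// final state and the acceptance count.
// [[Rcpp::export(name = ".cpp_mc_run")]]
List cpp_mc_run(NumericMatrix ca_r, NumericMatrix sc_r,
                NumericMatrix ca_p, NumericMatrix sc_p,
                IntegerVector type_r, IntegerVector type_p,
                NumericMatrix cmat,
                IntegerVector rest_i, IntegerVector rest_j,
                NumericVector rest_d, NumericVector rest_tol,
                NumericVector rest_slope,
                LogicalVector excluded, IntegerVector ss_p,
                IntegerVector chain_idx_r, NumericVector scd_p,
                List par, double temperature, int n_moves,
                List move_par) {
  EnergyParams p = read_params(par);
  const double bond_lo = move_par["bond_lo"], bond_hi = move_par["bond_hi"];
  const double d_single = move_par["d_single"];
  const double d_rigid_t = move_par["d_rigid_t"];
  const double a_rigid = move_par["a_rigid"];
  const double a_crank = move_par["a_crank"];
  const double d_receptor = move_par["d_receptor"];
  const bool receptor_moves = move_par["receptor_moves"];
  // spherical wall confining the peptide centroid (simulation volume)
  const double wall_radius = move_par["wall_radius"];
  const NumericVector wall_center = move_par["wall_center"];

  NumericMatrix car = clone(ca_r), scr = clone(sc_r);
  NumericMatrix cap = clone(ca_p), scp = clone(sc_p);
  const int np = cap.nrow(), nr = car.nrow();
  IntegerVector chain_idx_p(np, 1);
  canon_sc(cap, scd_p, scp);  // enforce the canonical side-chain rule

  NumericVector e = energy_impl(car, scr, cap, scp, type_r, type_p, cmat,
                                rest_i, rest_j, rest_d, rest_tol, rest_slope,
                                excluded, ss_p, p);
  double e_tot = e[0];
  int n_accept = 0;

  NumericMatrix ca_try(np, 3), sc_try(np, 3);
  NumericMatrix car_try(nr, 3), scr_try(nr, 3);

  for (int mv = 0; mv < n_moves; ++mv) {
    double u = unif_rand();
    bool moved_receptor = false;
    bool valid = true;

    // copy current peptide into proposal buffers
    for (int i = 0; i < np; ++i)
      for (int k = 0; k < 3; ++k) {
        ca_try(i, k) = cap(i, k);
        sc_try(i, k) = scp(i, k);
      }

    if (receptor_moves && u >= 0.75 && nr > 0) {
      // receptor single-Calpha displacement (side chain follows)
      moved_receptor = true;
      for (int i = 0; i < nr; ++i)
        for (int k = 0; k < 3; ++k) {
          car_try(i, k) = car(i, k);
          scr_try(i, k) = scr(i, k);
        }
      int i = (int)(unif_rand() * nr);
      if (i >= nr) i = nr - 1;
      double dv[3];
      ball_sample(d_receptor, dv);
      for (int k = 0; k < 3; ++k) {
        car_try(i, k) += dv[k];
        scr_try(i, k) += dv[k];
      }
      valid = bonds_ok(car_try, chain_idx_r, i, bond_lo, bond_hi);
    } else if (u < 0.35 || np < 3) {
      // peptide single-residue displacement
      int i = (int)(unif_rand() * np);
      if (i >= np) i = np - 1;
      double dv[3];
      ball_sample(d_single, dv);
      for (int k = 0; k < 3; ++k) {
        ca_try(i, k) += dv[k];
        sc_try(i, k) += dv[k];
      }
      valid = bonds_ok(ca_try, chain_idx_p, i, bond_lo, bond_hi);
    } else if (u < 0.60) {
      // crankshaft: rotate interior of a 2-4 bond fragment about its chord
      int gmax = (np - 1 < 4) ? np - 1 : 4;
      int g = 2 + (int)(unif_rand() * (gmax - 1));
      if (g > gmax) g = gmax;
      int i0 = (int)(unif_rand() * (np - g));
      if (i0 > np - 1 - g) i0 = np - 1 - g;
      int i1 = i0 + g;
      double axis[3];
      double n2 = 0;
      for (int k = 0; k < 3; ++k) {
        axis[k] = cap(i1, k) - cap(i0, k);
        n2 += axis[k] * axis[k];
      }
      double nn = std::sqrt(n2);
      if (nn < 1e-9) { valid = false; }
      else {
        for (int k = 0; k < 3; ++k) axis[k] /= nn;
        double ang = a_crank * (2 * unif_rand() - 1);
        double s = std::sin(ang), c = std::cos(ang);
        for (int i = i0 + 1; i < i1; ++i) {
          double x[3], y[3];
          for (int k = 0; k < 3; ++k) {
            x[k] = ca_try(i, k) - cap(i0, k);
            y[k] = sc_try(i, k) - cap(i0, k);
          }
          rotate_point(axis, s, c, x);
          rotate_point(axis, s, c, y);
          for (int k = 0; k < 3; ++k) {
            ca_try(i, k) = cap(i0, k) + x[k];
            sc_try(i, k) = cap(i0, k) + y[k];
          }
        }
      }
    } else {
      // rigid-body peptide rotation about centroid + translation
      double cen[3] = {0, 0, 0};
      for (int i = 0; i < np; ++i)
        for (int k = 0; k < 3; ++k) cen[k] += cap(i, k);
      for (int k = 0; k < 3; ++k) cen[k] /= np;
      double axis[3];
      double n2 = 0;
      for (int k = 0; k < 3; ++k) { axis[k] = norm_rand(); n2 += axis[k] * axis[k]; }
      double nn = std::sqrt(n2);
      for (int k = 0; k < 3; ++k) axis[k] /= nn;
      double ang = a_rigid * (2 * unif_rand() - 1);
      double s = std::sin(ang), c = std::cos(ang);
      double tv[3];
      ball_sample(d_rigid_t, tv);
      for (int i = 0; i < np; ++i) {
        double x[3], y[3];
        for (int k = 0; k < 3; ++k) {
          x[k] = cap(i, k) - cen[k];
          y[k] = scp(i, k) - cen[k];
        }
        rotate_point(axis, s, c, x);
        rotate_point(axis, s, c, y);
        for (int k = 0; k < 3; ++k) {
          ca_try(i, k) = cen[k] + x[k] + tv[k];
          sc_try(i, k) = cen[k] + y[k] + tv[k];
        }
      }
    }

    if (valid && !moved_receptor) {
      canon_sc(ca_try, scd_p, sc_try);
    }

    if (valid && !moved_receptor && R_finite(wall_radius)) {
      double cen[3] = {0, 0, 0};
      for (int i = 0; i < np; ++i)
        for (int k = 0; k < 3; ++k) cen[k] += ca_try(i, k);
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        cen[k] = cen[k] / np - wall_center[k];
        r2 += cen[k] * cen[k];
      }
      if (r2 > wall_radius * wall_radius) valid = false;
    }

    if (!valid) continue;

    NumericVector e_new = moved_receptor
      ? energy_impl(car_try, scr_try, cap, scp, type_r, type_p, cmat,
                    rest_i, rest_j, rest_d, rest_tol, rest_slope,
                    excluded, ss_p, p)
      : energy_impl(car, scr, ca_try, sc_try, type_r, type_p, cmat,
                    rest_i, rest_j, rest_d, rest_tol, rest_slope,
                    excluded, ss_p, p);
    double de = e_new[0] - e_tot;
    if (de <= 0 || unif_rand() < std::exp(-de / temperature)) {
      ++n_accept;
      e_tot = e_new[0];
      e = e_new;
      if (moved_receptor) {
        for (int i = 0; i < nr; ++i)
          for (int k = 0; k < 3; ++k) {
            car(i, k) = car_try(i, k);
            scr(i, k) = scr_try(i, k);
          }
      } else {
        for (int i = 0; i < np; ++i)
          for (int k = 0; k < 3; ++k) {
            cap(i, k) = ca_try(i, k);
            scp(i, k) = sc_try(i, k);
          }
      }
    }
  }

  return List::create(_["ca_r"] = car, _["sc_r"] = scr,
                      _["ca_p"] = cap, _["sc_p"] = scp,
                      _["energy"] = e, _["n_accept"] = n_accept);
}
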