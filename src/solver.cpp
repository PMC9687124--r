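// Explicit central-difference solver for hexahedral meshes with one-point
// quadrature, viscous hourglass control, rigid spherical-finger penalty
// contact and three part-wise constitutive models (neo-Hookean viscous
// flesh, von Mises plastic ribs, Ogden + Prony visco-hyperelastic liver).
// Units: mm, kg, ms -> stress GPa, force kN.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DN[8][3] = {  // dN/dxi at element centre
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

static const double HG[4][8] = {  // hourglass base vectors (eta*zeta, ...)
  {1, 1, -1, -1, -1, -1, 1, 1},
  {1, -1, -1, 1, -1, 1, 1, -1},
  {1, -1, 1, -1, 1, -1, 1, -1},
  {-1, 1, -1, 1, 1, -1, 1, -1}};

static inline double det3(const double A[3][3]) {
  return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
         A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
         A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
}

static inline void inv3(const double A[3][3], double J, double Ai[3][3]) {
  double id = 1.0 / J;
  Ai[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) * id;
  Ai[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) * id;
  Ai[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) * id;
  Ai[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) * id;
  Ai[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
}

// Jacobi eigen-decomposition of a symmetric 3x3 matrix.  V columns are
// eigenvectors; d eigenvalues (unsorted).
static void eig_sym3(const double Ain[3][3], double d[3], double V[3][3]) {
  double A[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { A[i][j] = Ain[i][j]; V[i][j] = (i == j); }
  for (int sweep = 0; sweep < 24; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    double dia = std::fabs(A[0][0]) + std::fabs(A[1][1]) + std::fabs(A[2][2]);
    if (off <= 1e-15 * (dia + 1e-300)) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        double apq = A[p][q];
        if (std::fabs(apq) < 1e-300) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) d[i] = A[i][i];
}

struct SymStore {  // order xx yy zz xy yz zx
  static inline void put(const double S[3][3], double *out) {
    out[0] = S[0][0]; out[1] = S[1][1]; out[2] = S[2][2];
    out[3] = S[0][1]; out[4] = S[1][2]; out[5] = S[0][2];
  }
};

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix nodes, IntegerMatrix elems,
                  IntegerVector part, IntegerVector fixed,
                  IntegerVector contact_nodes,
                  List flesh, List rib, List liver,
                  List fingers, double duration, double dt_in,
                  NumericVector stamps, double k_pen, double hg_coef,
                  double mass_damping, double mass_scaling_dt,
                  double z_top) {
  const int n = nodes.nrow(), m = elems.nrow();

  // material constants
  const double fl_rho = flesh["density"], fl_K = flesh["bulk_modulus"],
               fl_damp = flesh["damping"], fl_G = flesh["shear_modulus"];
  const double rb_rho = rib["density"], rb_E = rib["young_modulus"],
               rb_nu = rib["poisson"], rb_sy = rib["yield_stress"],
               rb_Et = rib["tangent_modulus"];
  const double rb_G = rb_E / (2 * (1 + rb_nu)),
               rb_K = rb_E / (3 * (1 - 2 * rb_nu)),
               rb_H = rb_E * rb_Et / (rb_E - rb_Et);
  NumericVector lv_mu = liver["mu"], lv_al = liver["alpha"];
  const int npr = as<NumericVector>(liver["prony_G"]).size();
  NumericVector lv_pG = liver["prony_G"], lv_ptau = liver["prony_tau"];
  const double lv_rho = liver["density"], lv_K = liver["bulk_modulus"],
               lv_mu0 = liver["shear0"];
  const int nog = lv_mu.size();

  // finger geometry / schedule
  const double fx = fingers["x"], fy = fingers["y"],
               half_sp = 0.5 * as<double>(fingers["spacing"]),
               R = fingers["radius"], depth = fingers["depth"],
               ramp = fingers["ramp"];

  // precompute element data
  std::vector<double> B0(m * 24), V0(m), gam(m * 32), rho_e(m), c_e(m);
  std::vector<double> mass(n, 0.0);
  double dt = dt_in;
  double scaled_mass = 0.0, total_mass = 0.0;
  for (int e = 0; e < m; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) X[a][i] = nodes(elems(e, a) - 1, i);
    double Jm[3][3] = {{0}};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int a = 0; a < 8; ++a) s += X[a][i] * DN[a][j] / 8.0;
        Jm[i][j] = s;
      }
    double dJ = det3(Jm);
    if (dJ <= 0) stop("degenerate element %d (non-positive Jacobian)", e + 1);
    V0[e] = 8.0 * dJ;
    double Ji[3][3];
    inv3(Jm, dJ, Ji);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int j = 0; j < 3; ++j) s += Ji[j][i] * DN[a][j] / 8.0;
        B0[e * 24 + a * 3 + i] = s;  // dN_a/dX_i
      }
    // hourglass vectors, orthogonalized against the linear field
    for (int k = 0; k < 4; ++k) {
      double hx[3] = {0, 0, 0};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) hx[i] += HG[k][a] * X[a][i];
      for (int a = 0; a < 8; ++a) {
        double g = HG[k][a];
        for (int i = 0; i < 3; ++i) g -= B0[e * 24 + a * 3 + i] * hx[i];
        gam[e * 32 + k * 8 + a] = g;
      }
    }
    double rho, K, G;
    if (part[e] == 3) { rho = lv_rho; K = lv_K; G = lv_mu0; }
    else if (part[e] == 2) { rho = rb_rho; K = rb_K; G = rb_G; }
    else { rho = fl_rho; K = fl_K; G = fl_G; }
    rho_e[e] = rho;
    c_e[e] = std::sqrt((K + 4.0 * G / 3.0) / rho);
    double me = rho * V0[e];
    total_mass += me;
    if (mass_scaling_dt > 0) {
      double h = std::cbrt(V0[e]);
      double dtw = h / c_e[e];                 // wave limit, scales as sqrt(f)
      double fac = (mass_scaling_dt / dtw) * (mass_scaling_dt / dtw);
      if (fac > 1.0) {
        scaled_mass += me * (fac - 1.0);
        me *= fac;
      }
    }
    for (int a = 0; a < 8; ++a) mass[elems(e, a) - 1] += me / 8.0;
  }

  // fixed node mask
  std::vector<char> is_fixed(n, 0);
  for (int i = 0; i < fixed.size(); ++i) is_fixed[fixed[i] - 1] = 1;

  // contact stability: the penalty spring on the lightest candidate node
  // must be resolved (dt < 2 sqrt(m/k), with margin)
  if (k_pen > 0 && contact_nodes.size() > 0) {
    double m_min = R_PosInf;
    for (int i = 0; i < contact_nodes.size(); ++i)
      m_min = std::min(m_min, mass[contact_nodes[i] - 1]);
    double dt_c = 0.5 * 2.0 * std::sqrt(m_min / k_pen);
    if (dt_c < dt) dt = dt_c;
  }
  const double dt_cap = dt;

  // state
  std::vector<double> u(3 * n, 0.0), v(3 * n, 0.0), f(3 * n, 0.0);
  std::vector<double> sig_out(m * 6, 0.0);
  std::vector<double> lv_h, lv_Elast;
  std::vector<int> lv_idx(m, -1);
  int nliv = 0;
  for (int e = 0; e < m; ++e) if (part[e] == 3) lv_idx[e] = nliv++;
  lv_h.assign((size_t)nliv * npr * 6, 0.0);
  lv_Elast.assign((size_t)nliv * 6, 0.0);
  std::vector<double> rb_sig(m * 6, 0.0), rb_ep(m, 0.0);  // ribs only use theirs

  // effective (possibly mass-scaled) densities for adaptive time stepping
  std::vector<double> rho_eff(m), h0(m);
  for (int e = 0; e < m; ++e) {
    h0[e] = std::cbrt(V0[e]);
    rho_eff[e] = rho_e[e];
    if (mass_scaling_dt > 0) {
      double dtw = h0[e] / c_e[e];
      double fac = (mass_scaling_dt / dtw) * (mass_scaling_dt / dtw);
      if (fac > 1.0) rho_eff[e] *= fac;
    }
  }

  double W_ext = 0, E_int = 0, E_diss = 0, E_contact = 0, KE = 0;
  double F_tot = 0, F_peak = 0;
  std::vector<double> force_hist, time_hist;
  List frames(stamps.size());
  int next_frame = 0;

  auto record_frame = [&](double t) {
    while (next_frame < stamps.size() &&
           stamps[next_frame] <= t + 1e-9) {
      NumericMatrix du(n, 3), st(m, 6);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j) du(i, j) = u[3 * i + j];
      for (int e = 0; e < m; ++e)
        for (int j = 0; j < 6; ++j) st(e, j) = sig_out[e * 6 + j];
      frames[next_frame] = List::create(
        _["time"] = t, _["disp"] = du, _["stress"] = st,
        _["force_kN"] = F_tot);
      ++next_frame;
    }
  };

  double t = 0.0;
  const double dt_floor = dt_in / 200.0;
  long nsteps = 0;
  for (;; ++nsteps) {
    // Adaptive step limit (every 20 steps): elements shrink and stiffen as
    // they deform, so the stable step is re-estimated from the current
    // minimum element dimension (h0 * smallest principal stretch) and, for
    // the liver, the current tangent of the Ogden stress.
    if (nsteps % 20 == 0) {
      double dt_req = dt_cap;
      for (int e = 0; e < m; ++e) {
        double F3[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        const double *B = &B0[e * 24];
        for (int a = 0; a < 8; ++a) {
          int nd = elems(e, a) - 1;
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              F3[i][j] += u[3 * nd + i] * B[a * 3 + j];
        }
        double C[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double sum = 0;
            for (int k = 0; k < 3; ++k) sum += F3[k][i] * F3[k][j];
            C[i][j] = sum;
          }
        double lam2[3], V[3][3];
        eig_sym3(C, lam2, V);
        double lmin2 = std::min(lam2[0], std::min(lam2[1], lam2[2]));
        double lmin = std::sqrt(std::max(lmin2, 1e-6));
        double h = h0[e] * std::min(lmin, 1.0);
        double K, G;
        if (part[e] == 3) {
          double J = det3(F3);
          double Jm13 = std::pow(std::max(J, 1e-6), -1.0 / 3.0);
          double Mstiff = 0;
          for (int p = 0; p < nog; ++p) {
            double lmax = 0;
            for (int i = 0; i < 3; ++i) {
              double lb = Jm13 * std::sqrt(std::max(lam2[i], 1e-6));
              double la = std::pow(lb, lv_al[p]);
              if (la > lmax) lmax = la;
            }
            Mstiff += std::fabs(lv_mu[p] * lv_al[p]) * lmax;
          }
          K = lv_K; G = lv_mu0 + Mstiff;
        } else if (part[e] == 2) { K = rb_K; G = rb_G; }
        else { K = fl_K; G = fl_G; }
        double cc = std::sqrt((K + 4.0 * G / 3.0) / rho_eff[e]);
        double d = 0.8 * h / cc;
        if (d < dt_req) dt_req = d;
      }
      dt = std::max(std::min(dt_req, dt_cap), dt_floor);
    }
    {
      double rem = duration - t;
      if (rem > 1e-12 && dt > rem) dt = rem;  // land exactly on the end time
    }

    std::fill(f.begin(), f.end(), 0.0);

    // --- contact with the two rigid finger tips ---
    double d_ind = depth * std::min(t / ramp, 1.0);
    double v_ind = (t < ramp) ? depth / ramp : 0.0;
    double cz = z_top + R - d_ind;
    double Fz = 0;
    E_contact = 0;
    for (int ci = 0; ci < contact_nodes.size(); ++ci) {
      int nd = contact_nodes[ci] - 1;
      double px = nodes(nd, 0) + u[3 * nd], py = nodes(nd, 1) + u[3 * nd + 1],
             pz = nodes(nd, 2) + u[3 * nd + 2];
      for (int fgr = 0; fgr < 2; ++fgr) {
        double cx = fx + (fgr == 0 ? -half_sp : half_sp);
        // fingertip = capsule: sphere of radius R capped by a vertical
        // cylindrical shaft above the centre
        double dx = px - cx, dy = py - fy,
               dz = (pz > cz) ? 0.0 : pz - cz;
        double dist2 = dx * dx + dy * dy + dz * dz;
        if (dist2 >= R * R || dist2 < 1e-20) continue;
        double dist = std::sqrt(dist2), pen = R - dist;
        double fmag = k_pen * pen, inv = 1.0 / dist;
        f[3 * nd] += fmag * dx * inv;
        f[3 * nd + 1] += fmag * dy * inv;
        f[3 * nd + 2] += fmag * dz * inv;
        Fz += fmag * (-dz * inv);  // reaction on finger, +z
        E_contact += 0.5 * k_pen * pen * pen;
      }
    }
    F_tot = Fz;
    if (F_tot > F_peak) F_peak = F_tot;
    W_ext += F_tot * v_ind * dt;

    // --- element internal + hourglass forces ---
    for (int e = 0; e < m; ++e) {
      int idx[8];
      double ue[8][3], ve[8][3];
      for (int a = 0; a < 8; ++a) {
        idx[a] = elems(e, a) - 1;
        for (int i = 0; i < 3; ++i) {
          ue[a][i] = u[3 * idx[a] + i];
          ve[a][i] = v[3 * idx[a] + i];
        }
      }
      const double *B = &B0[e * 24];
      double F3[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) F3[i][j] += ue[a][i] * B[a * 3 + j];
      double J = det3(F3);
      if (!(J > 1e-8))
        stop("element %d inverted at t = %g ms", e + 1, t);
      double Fi[3][3];
      inv3(F3, J, Fi);
      // spatial velocity gradient L = sum v_a (F^-T B0_a)
      double L[3][3] = {{0}};
      for (int a = 0; a < 8; ++a) {
        double b[3];
        for (int j = 0; j < 3; ++j) {
          b[j] = 0;
          for (int k = 0; k < 3; ++k) b[j] += B[a * 3 + k] * Fi[k][j];
        }
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) L[i][j] += ve[a][i] * b[j];
      }
      double D[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) D[i][j] = 0.5 * (L[i][j] + L[j][i]);

      double sig[3][3] = {{0}};
      if (part[e] == 1) {  // FLESH: neo-Hookean + viscosity
        double Jm23 = std::pow(J, -2.0 / 3.0);
        double Bt[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double sum = 0;
            for (int k = 0; k < 3; ++k) sum += F3[i][k] * F3[j][k];
            Bt[i][j] = Jm23 * sum;
          }
        double trB = (Bt[0][0] + Bt[1][1] + Bt[2][2]) / 3.0;
        double p = fl_K * (J - 1.0);
        // rate effects enter through the integrator's mass-proportional
        // damping (the card's damping coefficient), not a stress term
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double dd = (i == j);
            sig[i][j] = fl_G / J * (Bt[i][j] - trB * dd) + p * dd;
          }
      } else if (part[e] == 2) {  // RIB: radial-return plasticity
        double de[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) de[i][j] = D[i][j] * dt;
        double trde = de[0][0] + de[1][1] + de[2][2];
        double *sg = &rb_sig[e * 6];
        double st[3][3] = {{sg[0], sg[3], sg[5]},
                           {sg[3], sg[1], sg[4]},
                           {sg[5], sg[4], sg[2]}};
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            st[i][j] += 2 * rb_G * (de[i][j] - trde / 3.0 * (i == j)) +
                        rb_K * trde * (i == j);
        double tr = (st[0][0] + st[1][1] + st[2][2]) / 3.0;
        double sdev[3][3], s2 = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            sdev[i][j] = st[i][j] - tr * (i == j);
            s2 += sdev[i][j] * sdev[i][j];
          }
        double svm = std::sqrt(1.5 * s2);
        double fy = svm - (rb_sy + rb_H * rb_ep[e]);
        if (fy > 0 && svm > 0) {
          double dep = fy / (3 * rb_G + rb_H);
          double fac = 1.0 - 3 * rb_G * dep / svm;
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              st[i][j] = sdev[i][j] * fac + tr * (i == j);
          rb_ep[e] += dep;
        }
        SymStore::put(st, sg);
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) sig[i][j] = st[i][j];
      } else {  // LIVER: Ogden + Prony overstress on S
        double C[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double sum = 0;
            for (int k = 0; k < 3; ++k) sum += F3[k][i] * F3[k][j];
            C[i][j] = sum;
          }
        double lam2[3], N[3][3];
        eig_sym3(C, lam2, N);
        double lam[3], lb[3];
        double Jm13 = std::pow(J, -1.0 / 3.0);
        for (int i = 0; i < 3; ++i) {
          lam[i] = std::sqrt(std::max(lam2[i], 1e-12));
          lb[i] = Jm13 * lam[i];
        }
        double tau[3] = {0, 0, 0};
        for (int p = 0; p < nog; ++p) {
          double la[3], mn = 0;
          for (int i = 0; i < 3; ++i) { la[i] = std::pow(lb[i], lv_al[p]); mn += la[i]; }
          mn /= 3.0;
          for (int i = 0; i < 3; ++i) tau[i] += lv_mu[p] * (la[i] - mn);
        }
        double pvol = lv_K * (J - 1.0);
        double S[3][3] = {{0}};
        for (int i = 0; i < 3; ++i) {
          double Si = (tau[i] + J * pvol) / lam2[i];
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) S[a][b] += Si * N[a][i] * N[b][i];
        }
        // Prony overstress on deviatoric Green-Lagrange strain increment
        int li = lv_idx[e];
        double *El = &lv_Elast[(size_t)li * 6];
        double Enow[6] = {0.5 * (C[0][0] - 1), 0.5 * (C[1][1] - 1),
                          0.5 * (C[2][2] - 1), 0.5 * C[0][1], 0.5 * C[1][2],
                          0.5 * C[0][2]};
        double dE[6];
        for (int k = 0; k < 6; ++k) { dE[k] = Enow[k] - El[k]; El[k] = Enow[k]; }
        double trdE = (dE[0] + dE[1] + dE[2]) / 3.0;
        dE[0] -= trdE; dE[1] -= trdE; dE[2] -= trdE;
        double Sv[6] = {0, 0, 0, 0, 0, 0};
        for (int p = 0; p < npr; ++p) {
          double a = std::exp(-dt / lv_ptau[p]);
          double bcoef = lv_pG[p] * lv_ptau[p] / dt * (1.0 - a);
          double *h = &lv_h[((size_t)li * npr + p) * 6];
          for (int k = 0; k < 6; ++k) {
            h[k] = a * h[k] + bcoef * dE[k];
            Sv[k] += h[k];
          }
        }
        double Stot[3][3] = {{S[0][0] + Sv[0], S[0][1] + Sv[3], S[0][2] + Sv[5]},
                             {S[0][1] + Sv[3], S[1][1] + Sv[1], S[1][2] + Sv[4]},
                             {S[0][2] + Sv[5], S[1][2] + Sv[4], S[2][2] + Sv[2]}};
        // push forward: sigma = (1/J) F S F^T
        double FS[3][3] = {{0}};
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double sum = 0;
            for (int k = 0; k < 3; ++k) sum += F3[i][k] * Stot[k][j];
            FS[i][j] = sum;
          }
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double sum = 0;
            for (int k = 0; k < 3; ++k) sum += FS[i][k] * F3[j][k];
            sig[i][j] = sum / J;
          }
      }
      SymStore::put(sig, &sig_out[e * 6]);

      // internal force f_a -= V0 * P * B0_a, P = J sig F^-T
      double P[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double sum = 0;
          for (int k = 0; k < 3; ++k) sum += sig[i][k] * Fi[j][k];
          P[i][j] = J * sum;
        }
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double sum = 0;
          for (int j = 0; j < 3; ++j) sum += P[i][j] * B[a * 3 + j];
          f[3 * idx[a] + i] -= V0[e] * sum;
        }
      double sigD = 0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) sigD += sig[i][j] * D[i][j];
      E_int += V0[e] * J * sigD * dt;

      // viscous hourglass control
      if (hg_coef > 0) {
        double Qc = hg_coef * rho_e[e] * std::pow(V0[e], 2.0 / 3.0) *
                    c_e[e] * 0.25;
        const double *g = &gam[e * 32];
        for (int k = 0; k < 4; ++k) {
          double q[3] = {0, 0, 0};
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i) q[i] += g[k * 8 + a] * ve[a][i];
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i)
              f[3 * idx[a] + i] -= Qc * g[k * 8 + a] * q[i];
          E_diss += Qc * (q[0] * q[0] + q[1] * q[1] + q[2] * q[2]) * dt;
        }
      }
    }

    // state, stress and force are now all consistent at time t
    record_frame(t);
    force_hist.push_back(F_tot);
    time_hist.push_back(t);
    if (t >= duration - 1e-9) break;

    // --- damping, integration ---
    KE = 0;
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i]) {
        v[3 * i] = v[3 * i + 1] = v[3 * i + 2] = 0;
        continue;
      }
      double mi = mass[i];
      for (int j = 0; j < 3; ++j) {
        double vij = v[3 * i + j];
        double fd = mass_damping * mi * vij;
        E_diss += fd * vij * dt;
        double a = (f[3 * i + j] - fd) / mi;
        vij += a * dt;
        v[3 * i + j] = vij;
        u[3 * i + j] += vij * dt;
        KE += 0.5 * mi * vij * vij;
      }
    }

    if (nsteps % 200 == 0 && nsteps > 0) {
      if (!std::isfinite(KE) || !std::isfinite(E_int))
        stop("instability: non-finite energy at t = %g ms", t);
      if (W_ext > 1e-9 && KE > 10.0 * W_ext)
        stop("instability: kinetic energy exceeds 10x external work at t = %g ms", t);
    }
    t += dt;
  }

  return List::create(
    _["frames"] = frames,
    _["force_t"] = NumericVector(time_hist.begin(), time_hist.end()),
    _["force_kN"] = NumericVector(force_hist.begin(), force_hist.end()),
    _["energy"] = List::create(_["external_work"] = W_ext,
                               _["kinetic"] = KE, _["internal"] = E_int,
                               _["contact"] = E_contact,
                               _["dissipated"] = E_diss),
    _["peak_force_kN"] = F_peak,
    _["dt"] = dt_in, _["dt_final"] = dt, _["n_steps"] = (double)nsteps,
    _["added_mass_fraction"] = scaled_mass / total_mass);
}
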