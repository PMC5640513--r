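// Membrane finite-element kernel for the pressurized guard-cell wall.
//
// Total potential energy and its analytic gradient for a triangulated
// hyperelastic membrane (incompressible plane-stress Veronda-Westmann
// matrix + one in-plane fiber family), conservative pressure potentials
// (enclosed-volume flux per loaded face), discrete-hinge bending
// regularization, and a midplane no-penetration penalty. Units: um, MPa;
// energy in MPa*um^3 (pJ), forces in uN.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GL_X[8] = {
  -0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
  -0.1834346424956498,  0.1834346424956498,  0.5255324099163290,
   0.7966664774136267,  0.9602898564975363};
static const double GL_W[8] = {
  0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
  0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
  0.2223810344533745, 0.1012285362903763};

struct Mat {
  double C1, C2, C3, C4, C5, ls, C6;
};

// fiber force lambda * dWf/dlambda (piecewise toe/linear law)
static inline double fiber_force(double l, const Mat& m) {
  if (l <= 1.0) return 0.0;
  if (l < m.ls) return m.C3 * (std::exp(m.C4 * (l - 1.0)) - 1.0);
  return m.C5 * l + m.C6;
}

// fiber energy: Gauss-Legendre on the toe, closed form on the linear branch
static inline double fiber_energy(double l, const Mat& m) {
  if (l <= 1.0 || (m.C3 == 0.0 && m.C5 == 0.0)) return 0.0;
  double toe_end = std::min(l, m.ls);
  double W = 0.0;
  if (toe_end > 1.0 && m.C3 > 0.0) {
    double a = 1.0, b = toe_end, h = 0.5 * (b - a), c = 0.5 * (a + b);
    for (int k = 0; k < 8; ++k) {
      double t = c + h * GL_X[k];
      W += h * GL_W[k] * m.C3 * (std::exp(m.C4 * (t - 1.0)) - 1.0) / t;
    }
  }
  if (l > m.ls) {
    W += m.C5 * (l - m.ls) + m.C6 * std::log(l / m.ls);
  }
  return W;
}

// [[Rcpp::export]]
List mem_energy_grad(NumericVector x,
                     IntegerMatrix elems,      // m x 3, 1-based
                     NumericMatrix Ginv,       // m x 4: g11,g21,g12,g22
                     NumericVector A0,         // reference areas
                     NumericVector thick,      // element thickness
                     NumericMatrix a2d,        // m x 2 local fiber components
                     NumericVector pcoef,      // m: pressure flux coefficient (MPa)
                     NumericVector mat,        // C1,C2,C3,C4,C5,ls,C6
                     IntegerMatrix hinges,     // h x 4: x0,x1,x2,x3 (1-based), may have 0 rows
                     NumericVector kh,         // h hinge stiffnesses
                     NumericVector theta0,     // h rest dihedrals
                     IntegerVector cnode,      // contact nodes (1-based)
                     NumericVector csign,      // +1 keep y>=0, -1 keep y<=0
                     NumericVector kc,         // per-node penalty (area-weighted)
                     bool want_grad) {
  const int m = elems.nrow();
  const int n = x.size() / 3;
  Mat mp = {mat[0], mat[1], mat[2], mat[3], mat[4], mat[5], mat[6]};

  NumericVector grad(want_grad ? 3 * n : 0);
  double E_mem = 0.0, E_press = 0.0, E_bend = 0.0, E_contact = 0.0;
  bool degenerate = false;

  const double* X = x.begin();
  double* G = want_grad ? grad.begin() : nullptr;

  for (int e = 0; e < m; ++e) {
    const int n1 = elems(e, 0) - 1, n2 = elems(e, 1) - 1, n3 = elems(e, 2) - 1;
    const double* x1 = X + 3 * n1;
    const double* x2 = X + 3 * n2;
    const double* x3 = X + 3 * n3;
    double d1[3], d2[3];
    for (int k = 0; k < 3; ++k) { d1[k] = x2[k] - x1[k]; d2[k] = x3[k] - x1[k]; }
    const double g11 = Ginv(e, 0), g21 = Ginv(e, 1), g12 = Ginv(e, 2), g22 = Ginv(e, 3);
    double f1[3], f2[3];
    for (int k = 0; k < 3; ++k) {
      f1[k] = g11 * d1[k] + g21 * d2[k];
      f2[k] = g12 * d1[k] + g22 * d2[k];
    }
    double C11 = 0, C22 = 0, C12 = 0;
    for (int k = 0; k < 3; ++k) {
      C11 += f1[k] * f1[k]; C22 += f2[k] * f2[k]; C12 += f1[k] * f2[k];
    }
    double det = C11 * C22 - C12 * C12;
    if (!(det > 1e-8) || !std::isfinite(det)) { degenerate = true; continue; }
    double tr = C11 + C22;
    double I1 = tr + 1.0 / det;
    double expt = std::exp(mp.C2 * (I1 - 3.0));
    if (!std::isfinite(expt) || expt > 1e12) { degenerate = true; continue; }
    double I2 = det + tr / det;
    double Wm = mp.C1 * (expt - 1.0) - 0.5 * mp.C1 * mp.C2 * (I2 - 3.0);
    double W1 = mp.C1 * mp.C2 * expt;
    double W2 = -0.5 * mp.C1 * mp.C2;

    // fiber
    const double a1 = a2d(e, 0), a2 = a2d(e, 1);
    double I4 = a1 * a1 * C11 + 2.0 * a1 * a2 * C12 + a2 * a2 * C22;
    double lam = std::sqrt(I4);
    double Wf = fiber_energy(lam, mp);

    double At = A0[e] * thick[e];
    E_mem += At * (Wm + Wf);

    if (want_grad) {
      // S = dW/dC (2x2 symmetric)
      double id2 = 1.0 / (det * det);
      double invd = 1.0 / det;
      // adj(C) = [C22, -C12; -C12, C11]; Cinv = adj/det
      // dI1/dC = I - (1/d) Cinv ; Cinv = adj/d => (1/d)Cinv = adj/d^2
      double S11 = W1 * (1.0 - C22 * id2) + W2 * (C22 + invd - tr * C22 * id2);
      double S22 = W1 * (1.0 - C11 * id2) + W2 * (C11 + invd - tr * C11 * id2);
      double S12 = W1 * (C12 * id2) + W2 * (-C12 + tr * C12 * id2);
      if (lam > 1.0) {
        double dWfdl = fiber_force(lam, mp) / lam;
        double c = dWfdl / (2.0 * lam);
        S11 += c * a1 * a1;
        S22 += c * a2 * a2;
        S12 += c * a1 * a2;
      }
      // dE/dF_s = At * 2 F S ; columns p1, p2
      double p1[3], p2[3];
      for (int k = 0; k < 3; ++k) {
        p1[k] = 2.0 * At * (S11 * f1[k] + S12 * f2[k]);
        p2[k] = 2.0 * At * (S12 * f1[k] + S22 * f2[k]);
      }
      // dE/dd1 = p1 g11 + p2 g12 ; dE/dd2 = p1 g21 + p2 g22
      for (int k = 0; k < 3; ++k) {
        double gd1 = p1[k] * g11 + p2[k] * g12;
        double gd2 = p1[k] * g21 + p2[k] * g22;
        G[3 * n2 + k] += gd1;
        G[3 * n3 + k] += gd2;
        G[3 * n1 + k] -= gd1 + gd2;
      }
    }

    // pressure flux potential: cp/6 * x1 . (x2 x x3)
    double cp = pcoef[e];
    if (cp != 0.0) {
      double c23[3] = {x2[1] * x3[2] - x2[2] * x3[1],
                       x2[2] * x3[0] - x2[0] * x3[2],
                       x2[0] * x3[1] - x2[1] * x3[0]};
      double triple = x1[0] * c23[0] + x1[1] * c23[1] + x1[2] * c23[2];
      E_press += cp / 6.0 * triple;
      if (want_grad) {
        double c31[3] = {x3[1] * x1[2] - x3[2] * x1[1],
                         x3[2] * x1[0] - x3[0] * x1[2],
                         x3[0] * x1[1] - x3[1] * x1[0]};
        double c12[3] = {x1[1] * x2[2] - x1[2] * x2[1],
                         x1[2] * x2[0] - x1[0] * x2[2],
                         x1[0] * x2[1] - x1[1] * x2[0]};
        for (int k = 0; k < 3; ++k) {
          G[3 * n1 + k] += cp / 6.0 * c23[k];
          G[3 * n2 + k] += cp / 6.0 * c31[k];
          G[3 * n3 + k] += cp / 6.0 * c12[k];
        }
      }
    }
  }

  // discrete-hinge bending
  const int nh = hinges.nrow();
  for (int hgi = 0; hgi < nh; ++hgi) {
    const int i0 = hinges(hgi, 0) - 1, i1 = hinges(hgi, 1) - 1,
              i2 = hinges(hgi, 2) - 1, i3 = hinges(hgi, 3) - 1;
    const double* p0 = X + 3 * i0;
    const double* p1 = X + 3 * i1;
    const double* p2 = X + 3 * i2;
    const double* p3 = X + 3 * i3;
    double e0[3], v2[3], v3[3];
    for (int k = 0; k < 3; ++k) {
      e0[k] = p1[k] - p0[k];
      v2[k] = p2[k] - p0[k];
      v3[k] = p3[k] - p0[k];
    }
    double nA[3] = {e0[1] * v2[2] - e0[2] * v2[1],
                    e0[2] * v2[0] - e0[0] * v2[2],
                    e0[0] * v2[1] - e0[1] * v2[0]};
    double nB[3] = {v3[1] * e0[2] - v3[2] * e0[1],
                    v3[2] * e0[0] - v3[0] * e0[2],
                    v3[0] * e0[1] - v3[1] * e0[0]};
    double le = std::sqrt(e0[0] * e0[0] + e0[1] * e0[1] + e0[2] * e0[2]);
    double nA2 = nA[0] * nA[0] + nA[1] * nA[1] + nA[2] * nA[2];
    double nB2 = nB[0] * nB[0] + nB[1] * nB[1] + nB[2] * nB[2];
    if (le < 1e-12 || nA2 < 1e-20 || nB2 < 1e-20) { degenerate = true; continue; }
    double cx[3] = {nA[1] * nB[2] - nA[2] * nB[1],
                    nA[2] * nB[0] - nA[0] * nB[2],
                    nA[0] * nB[1] - nA[1] * nB[0]};
    double sinn = (cx[0] * e0[0] + cx[1] * e0[1] + cx[2] * e0[2]) / le;
    double coss = nA[0] * nB[0] + nA[1] * nB[1] + nA[2] * nB[2];
    double th = std::atan2(sinn, coss);
    double dth = th - theta0[hgi];
    E_bend += kh[hgi] * dth * dth;
    if (want_grad) {
      double coef = 2.0 * kh[hgi] * dth;
      double w2 = le / nA2, w3 = le / nB2;
      double dot12 = ((p1[0] - p2[0]) * e0[0] + (p1[1] - p2[1]) * e0[1] +
                      (p1[2] - p2[2]) * e0[2]) / le;
      double dot13 = ((p1[0] - p3[0]) * e0[0] + (p1[1] - p3[1]) * e0[1] +
                      (p1[2] - p3[2]) * e0[2]) / le;
      double dot02 = ((p0[0] - p2[0]) * e0[0] + (p0[1] - p2[1]) * e0[1] +
                      (p0[2] - p2[2]) * e0[2]) / le;
      double dot03 = ((p0[0] - p3[0]) * e0[0] + (p0[1] - p3[1]) * e0[1] +
                      (p0[2] - p3[2]) * e0[2]) / le;
      for (int k = 0; k < 3; ++k) {
        double gA = nA[k] / nA2, gB = nB[k] / nB2;
        G[3 * i2 + k] += coef * (-w2 * nA[k]);
        G[3 * i3 + k] += coef * (-w3 * nB[k]);
        G[3 * i0 + k] += coef * (dot12 * gA + dot13 * gB);
        G[3 * i1 + k] += coef * (-dot02 * gA - dot03 * gB);
      }
    }
  }

  // midplane no-penetration penalty
  const int nc = cnode.size();
  for (int i = 0; i < nc; ++i) {
    int nd = cnode[i] - 1;
    double s = csign[i];
    double y = X[3 * nd + 1];
    double v = s * y;
    if (v < 0.0) {
      E_contact += kc[i] * v * v;
      if (want_grad) G[3 * nd + 1] += 2.0 * kc[i] * v * s;
    }
  }

  double E = E_mem + E_press + E_bend + E_contact;
  if (degenerate) E = 1e12;
  return List::create(_["E"] = E, _["grad"] = grad,
                      _["E_mem"] = E_mem, _["E_press"] = E_press,
                      _["E_bend"] = E_bend, _["E_contact"] = E_contact,
                      _["degenerate"] = degenerate);
}

// Full objective for the reduced (tied/fixed-dof) system: expands the
// optimization vector into nodal coordinates, evaluates the membrane
// kernel, adds the weak rigid-body-mode penalty, and returns the energy
// with the gradient already reduced onto the optimization vector.
// parmap: for each full dof, 0-based index into par, or -1 (fixed).
// r0: reference coordinates minus centroid (3n); L2: mean squared radius.
// [[Rcpp::export]]
List mem_objective(NumericVector par,
                   NumericVector xtemplate,
                   IntegerVector parmap,
                   NumericVector x0ref,
                   NumericVector r0,
                   double kr, double L2,
                   IntegerMatrix elems, NumericMatrix Ginv,
                   NumericVector A0, NumericVector thick,
                   NumericMatrix a2d, NumericVector pcoef,
                   NumericVector mat, IntegerMatrix hinges,
                   NumericVector kh, NumericVector theta0,
                   IntegerVector cnode, NumericVector csign,
                   NumericVector kc) {
  const int nd = xtemplate.size();
  const int n = nd / 3;
  NumericVector x(nd);
  for (int i = 0; i < nd; ++i) {
    x[i] = parmap[i] >= 0 ? par[parmap[i]] : xtemplate[i];
  }
  List res = mem_energy_grad(x, elems, Ginv, A0, thick, a2d, pcoef, mat,
                             hinges, kh, theta0, cnode, csign, kc, true);
  NumericVector g = res["grad"];
  double E = res["E"];
  // rigid-mode penalty: kr * (|sum u|^2 + |sum r x u|^2 / L2) / n
  double su[3] = {0, 0, 0}, cr[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    double u0 = x[3 * i] - x0ref[3 * i];
    double u1 = x[3 * i + 1] - x0ref[3 * i + 1];
    double u2 = x[3 * i + 2] - x0ref[3 * i + 2];
    su[0] += u0; su[1] += u1; su[2] += u2;
    const double rx = r0[3 * i], ry = r0[3 * i + 1], rz = r0[3 * i + 2];
    cr[0] += ry * u2 - rz * u1;
    cr[1] += rz * u0 - rx * u2;
    cr[2] += rx * u1 - ry * u0;
  }
  double E_r = kr * (su[0] * su[0] + su[1] * su[1] + su[2] * su[2] +
                     (cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]) / L2) / n;
  const double ct = 2.0 * kr / n;
  const double cm = 2.0 * kr / (n * L2);
  for (int i = 0; i < n; ++i) {
    const double rx = r0[3 * i], ry = r0[3 * i + 1], rz = r0[3 * i + 2];
    g[3 * i]     += ct * su[0] + cm * (cr[1] * rz - cr[2] * ry);
    g[3 * i + 1] += ct * su[1] + cm * (cr[2] * rx - cr[0] * rz);
    g[3 * i + 2] += ct * su[2] + cm * (cr[0] * ry - cr[1] * rx);
  }
  NumericVector gred(par.size());
  for (int i = 0; i < nd; ++i) {
    if (parmap[i] >= 0) gred[parmap[i]] += g[i];
  }
  return List::create(_["E"] = E + E_r, _["grad"] = gred,
                      _["E_mem"] = res["E_mem"], _["E_press"] = res["E_press"],
                      _["E_bend"] = res["E_bend"],
                      _["E_contact"] = res["E_contact"],
                      _["degenerate"] = res["degenerate"]);
}
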