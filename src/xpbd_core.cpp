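// XPBD constraint kernels and the quasi-static Gauss-Seidel loop.
//
// Conventions: positions are stored node-major (x[3*i + axis], mm); node
// masses in kg (invmass = 1/mass, 0 for pinned nodes); per-axis free mask
// multiplies displacement components (1 = free, 0 = held). Compliances are
// the XPBD alpha (inverse stiffness); alpha_tilde = alpha / dt_sub^2.
// Infinite viscous damping: there is no inertial predictor, the candidate
// position of every substep is the current position, so dt is purely a
// schedule clock.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// 3x3 column-major: m[col*3 + row]
static inline double det3(const double* m) {
  return m[0] * (m[4] * m[8] - m[7] * m[5])
       - m[3] * (m[1] * m[8] - m[7] * m[2])
       + m[6] * (m[1] * m[5] - m[4] * m[2]);
}

static inline bool inv3(const double* m, double* o) {
  double d = det3(m);
  if (d == 0.0 || !std::isfinite(d)) return false;
  double id = 1.0 / d;
  o[0] =  (m[4] * m[8] - m[7] * m[5]) * id;
  o[1] = -(m[1] * m[8] - m[7] * m[2]) * id;
  o[2] =  (m[1] * m[5] - m[4] * m[2]) * id;
  o[3] = -(m[3] * m[8] - m[6] * m[5]) * id;
  o[4] =  (m[0] * m[8] - m[6] * m[2]) * id;
  o[5] = -(m[0] * m[5] - m[3] * m[2]) * id;
  o[6] =  (m[3] * m[7] - m[6] * m[4]) * id;
  o[7] = -(m[0] * m[7] - m[6] * m[1]) * id;
  o[8] =  (m[0] * m[4] - m[3] * m[1]) * id;
  return true;
}

// Edge matrix Ds = [x1-x0 | x2-x0 | x3-x0], column-major.
static inline void edge_matrix(const double* X, const int* v, double* Ds) {
  const double* p0 = X + 3 * v[0];
  for (int c = 0; c < 3; ++c) {
    const double* pc = X + 3 * v[c + 1];
    Ds[3 * c + 0] = pc[0] - p0[0];
    Ds[3 * c + 1] = pc[1] - p0[1];
    Ds[3 * c + 2] = pc[2] - p0[2];
  }
}

// Generic XPBD position update for one constraint with value C and per-node
// gradients g[4][3] (node k participates iff v[k] >= 0). Returns |C|.
// `cap` bounds the displacement of any single node in one projection (a
// stability safeguard for very light boundary nodes; it is inactive at
// convergence, where dlambda -> 0, so fixed points are unaffected).
static inline double xpbd_apply(double* X, const double* w, const double* fm,
                                const int* v, int nn, double C,
                                double g[][3], double alpha_t, double* lambda,
                                double cap, bool variational = false) {
  double wsum = 0.0, wmaxg2 = 0.0;
  for (int k = 0; k < nn; ++k) {
    int i = v[k];
    double wi = w[i];
    if (wi == 0.0) continue;
    const double* m = fm + 3 * i;
    double s = 0.0;
    for (int a = 0; a < 3; ++a) {
      double ga = g[k][a] * m[a];
      s += ga * ga;
    }
    wsum += wi * s;
    double wg = wi * wi * s;   // |w_i * g_i|^2
    if (wg > wmaxg2) wmaxg2 = wg;
  }
  // variational mode: compliant-limit denominator (pure alpha_t), making a
  // sweep an exact mass-preconditioned gradient-descent pass on the total
  // constraint energy (denominators proportional to the true compliances,
  // so forces of unequal-stiffness families balance exactly at critical
  // points); canonical mode: the standard XPBD denominator
  double denom = variational ? alpha_t : (wsum + alpha_t);
  if (denom <= 0.0 || wsum == 0.0) return std::fabs(C);  // fully pinned / degenerate
  double dlam = (-C - alpha_t * (*lambda)) / denom;
  double maxdisp = std::fabs(dlam) * std::sqrt(wmaxg2);
  if (maxdisp > cap) dlam *= cap / maxdisp;
  *lambda += dlam;
  for (int k = 0; k < nn; ++k) {
    int i = v[k];
    double wi = w[i];
    if (wi == 0.0) continue;
    const double* m = fm + 3 * i;
    double* xi = X + 3 * i;
    for (int a = 0; a < 3; ++a) xi[a] += wi * dlam * g[k][a] * m[a];
  }
  return std::fabs(C);
}

// Hydrostatic constraint C_H = det(Ds)/(6 V0) - gamma (volume memory: V0 is
// the original rest volume, untouched by viscoelastic rest-pose relaxation;
// gamma = 1 is the plain neo-Hookean target, gamma = 1 + mu/lambda the
// rest-stabilized stable-constraint variant).
static inline double proj_tet_H(double* X, const double* w, const double* fm,
                                const int* v, double V0, double gamma,
                                double alpha_t, double* lambda, double cap,
                                double* detDs_out) {
  double Ds[9];
  edge_matrix(X, v, Ds);
  double detDs = det3(Ds);
  if (detDs_out) *detDs_out = detDs;
  double iv = 1.0 / (6.0 * V0);
  double C = detDs * iv - gamma;
  double g[4][3];
  // grad wrt x1 = (e2 x e3)/(6V0), x2 = (e3 x e1)/(6V0), x3 = (e1 x e2)/(6V0)
  cross3(Ds + 3, Ds + 6, g[1]);
  cross3(Ds + 6, Ds + 0, g[2]);
  cross3(Ds + 0, Ds + 3, g[3]);
  for (int a = 0; a < 3; ++a) {
    g[1][a] *= iv; g[2][a] *= iv; g[3][a] *= iv;
    g[0][a] = -(g[1][a] + g[2][a] + g[3][a]);
  }
  return xpbd_apply(X, w, fm, v, 4, C, g, alpha_t, lambda, cap);
}

// Deviatoric constraint C_D = sqrt(tr(F^T F)), F = Ds * DmInv (stable
// neo-Hookean split; DmInv reflects the viscoelastically relaxed rest pose).
static inline double proj_tet_D(double* X, const double* w, const double* fm,
                                const int* v, const double* DmInv,
                                double alpha_t, double* lambda, double cap) {
  double Ds[9];
  edge_matrix(X, v, Ds);
  double F[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      F[3 * c + r] = Ds[r] * DmInv[3 * c] + Ds[3 + r] * DmInv[3 * c + 1]
                   + Ds[6 + r] * DmInv[3 * c + 2];
  double tr = 0.0;
  for (int k = 0; k < 9; ++k) tr += F[k] * F[k];
  double C = std::sqrt(tr);
  if (C < 1e-14) return 0.0;  // fully collapsed: gradient undefined, skip
  // dC/dDs = (F * DmInv^T) / C ; grad wrt x_j (j=1..3) is column j of that
  double g[4][3];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      g[c + 1][r] = (F[r] * DmInv[c] + F[3 + r] * DmInv[3 + c]
                   + F[6 + r] * DmInv[6 + c]) / C;
  for (int a = 0; a < 3; ++a) g[0][a] = -(g[1][a] + g[2][a] + g[3][a]);
  return xpbd_apply(X, w, fm, v, 4, C, g, alpha_t, lambda, cap);
}

// Surface-area constraint C = 0.5*||(x2-x1) x (x3-x1)|| - R.
static inline double proj_area(double* X, const double* w, const double* fm,
                               const int* v, double R, double alpha_t,
                               double* lambda, double cap,
                               bool variational = false) {
  const double* x1 = X + 3 * v[0];
  const double* x2 = X + 3 * v[1];
  const double* x3 = X + 3 * v[2];
  double e12[3], e13[3], n[3];
  for (int a = 0; a < 3; ++a) { e12[a] = x2[a] - x1[a]; e13[a] = x3[a] - x1[a]; }
  cross3(e12, e13, n);
  double nn = std::sqrt(dot3(n, n));
  if (nn < 1e-14) return 0.0;  // degenerate face, skip
  double C = 0.5 * nn - R;
  double nh[3] = { n[0] / nn, n[1] / nn, n[2] / nn };
  double g[4][3];
  double e23[3] = { x3[0] - x2[0], x3[1] - x2[1], x3[2] - x2[2] };
  double e31[3] = { x1[0] - x3[0], x1[1] - x3[1], x1[2] - x3[2] };
  double e21[3] = { x1[0] - x2[0], x1[1] - x2[1], x1[2] - x2[2] };
  // grad_{x1} = 0.5 (x2-x3) x nh, grad_{x2} = 0.5 (x3-x1) x nh,
  // grad_{x3} = 0.5 (x1-x2) x nh
  double t[3];
  t[0] = -e23[0]; t[1] = -e23[1]; t[2] = -e23[2];
  cross3(t, nh, g[0]);
  t[0] = -e31[0]; t[1] = -e31[1]; t[2] = -e31[2];
  cross3(t, nh, g[1]);
  cross3(e21, nh, g[2]);
  for (int k = 0; k < 3; ++k)
    for (int a = 0; a < 3; ++a) g[k][a] *= 0.5;
  return xpbd_apply(X, w, fm, v, 3, C, g, alpha_t, lambda, cap, variational);
}

// Smoothing constraint over two triangles sharing edge (s0,s1) with opposite
// vertices a,b: C = 0.5*||(a+b)-(s0+s1)|| - L.
static inline double proj_smooth(double* X, const double* w, const double* fm,
                                 const int* v, double L, double alpha_t,
                                 double* lambda, double cap,
                                 bool variational = false) {
  const double* a = X + 3 * v[0];
  const double* s0 = X + 3 * v[1];
  const double* s1 = X + 3 * v[2];
  const double* b = X + 3 * v[3];
  double d[3];
  for (int k = 0; k < 3; ++k) d[k] = (a[k] + b[k]) - (s0[k] + s1[k]);
  double nd = std::sqrt(dot3(d, d));
  if (nd < 1e-14) return 0.0;  // coincident midpoints: gradient undefined
  double C = 0.5 * nd - L;
  double u[3] = { d[0] / nd, d[1] / nd, d[2] / nd };
  double g[4][3];
  for (int k = 0; k < 3; ++k) {
    g[0][k] = 0.5 * u[k];
    g[1][k] = -0.5 * u[k];
    g[2][k] = -0.5 * u[k];
    g[3][k] = 0.5 * u[k];
  }
  return xpbd_apply(X, w, fm, v, 4, C, g, alpha_t, lambda, cap, variational);
}

// Fused projection of one tet's hydrostatic + deviatoric constraint pair:
// both multiplier updates are computed from the same positions and the two
// displacements applied together. At a critical point of the element energy
// the combined displacement vanishes exactly, which removes the systematic
// drift that alternating single projections of two mutually canceling
// constraints would produce (their values never vanish at rest).
static inline void proj_tet_pair(double* X, const double* w, const double* fm,
                                 const int* v, const double* DmInv, double V0,
                                 double gamma, double aH_t, double aD_t,
                                 double* lamH, double* lamD, double cap,
                                 double* absCH, double* devD,
                                 double* detDs_out) {
  double Ds[9];
  edge_matrix(X, v, Ds);
  double detDs = det3(Ds);
  if (detDs_out) *detDs_out = detDs;
  double iv = 1.0 / (6.0 * V0);
  double CH = detDs * iv - gamma;
  double gH[4][3];
  cross3(Ds + 3, Ds + 6, gH[1]);
  cross3(Ds + 6, Ds + 0, gH[2]);
  cross3(Ds + 0, Ds + 3, gH[3]);
  for (int a = 0; a < 3; ++a) {
    gH[1][a] *= iv; gH[2][a] *= iv; gH[3][a] *= iv;
    gH[0][a] = -(gH[1][a] + gH[2][a] + gH[3][a]);
  }
  double F[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      F[3 * c + r] = Ds[r] * DmInv[3 * c] + Ds[3 + r] * DmInv[3 * c + 1]
                   + Ds[6 + r] * DmInv[3 * c + 2];
  double tr = 0.0;
  for (int k = 0; k < 9; ++k) tr += F[k] * F[k];
  double CD = std::sqrt(tr);
  *absCH = std::fabs(CH);
  *devD = std::fabs(CD - std::sqrt(3.0));
  bool doD = CD > 1e-14;
  double gD[4][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
  if (doD) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        gD[c + 1][r] = (F[r] * DmInv[c] + F[3 + r] * DmInv[3 + c]
                     + F[6 + r] * DmInv[6 + c]) / CD;
    for (int a = 0; a < 3; ++a)
      gD[0][a] = -(gD[1][a] + gD[2][a] + gD[3][a]);
  }
  double wsumH = 0.0, wsumD = 0.0, wmaxH2 = 0.0, wmaxD2 = 0.0;
  for (int k = 0; k < 4; ++k) {
    int i = v[k];
    double wi = w[i];
    if (wi == 0.0) continue;
    const double* m = fm + 3 * i;
    double sH = 0.0, sD = 0.0;
    for (int a = 0; a < 3; ++a) {
      double gh = gH[k][a] * m[a], gd = gD[k][a] * m[a];
      sH += gh * gh;
      sD += gd * gd;
    }
    wsumH += wi * sH;
    wsumD += wi * sD;
    if (wi * wi * sH > wmaxH2) wmaxH2 = wi * wi * sH;
    if (wi * wi * sD > wmaxD2) wmaxD2 = wi * wi * sD;
  }
  // compliant-limit (variational) multiplier updates: denominators are the
  // pure alpha_t, so the combined move is a gradient step of the element
  // energy and vanishes exactly at its critical points (e.g. the rest pose
  // with the rest-stabilized hydrostatic target)
  double dlamH = 0.0, dlamD = 0.0;
  if (wsumH > 0.0 && aH_t > 0.0) {
    dlamH = (-CH - aH_t * (*lamH)) / aH_t;
    double md = std::fabs(dlamH) * std::sqrt(wmaxH2);
    if (md > cap) dlamH *= cap / md;
    *lamH += dlamH;
  }
  if (doD && wsumD > 0.0 && aD_t > 0.0) {
    dlamD = (-CD - aD_t * (*lamD)) / aD_t;
    double md = std::fabs(dlamD) * std::sqrt(wmaxD2);
    if (md > cap) dlamD *= cap / md;
    *lamD += dlamD;
  }
  for (int k = 0; k < 4; ++k) {
    int i = v[k];
    double wi = w[i];
    if (wi == 0.0) continue;
    const double* m = fm + 3 * i;
    double* xi = X + 3 * i;
    for (int a = 0; a < 3; ++a)
      xi[a] += wi * (dlamH * gH[k][a] + dlamD * gD[k][a]) * m[a];
  }
}

// ---------------------------------------------------------------------------
// Full quasi-static loop over a chunk of steps.
//
// Per step: advance schedules (restA *= facA[k], restL *= facL[k]); run
// `substeps` XPBD substeps, each `iterations` Gauss-Seidel sweeps with
// persistent Lagrange multipliers (reset at substep start); then apply the
// viscoelastic rest-pose blend Dm <- (1-kappa) Dm + kappa Ds,
// kappa = 1 - exp(-beta dt). Sweep order: tets (H then D per tet), area,
// smoothing, in index order (deterministic).
// [[Rcpp::export]]
List cpp_xpbd_advance(NumericVector x, NumericVector invmass,
                      NumericVector freemask, IntegerMatrix tets,
                      NumericVector Dm, NumericVector restvol,
                      NumericVector gammaH,
                      NumericVector alphaH, NumericVector alphaD,
                      IntegerMatrix faces, NumericVector restA,
                      NumericVector alphaA, IntegerMatrix quads,
                      NumericVector restL, NumericVector alphaS,
                      NumericVector facA, NumericVector facL,
                      int substeps, int iterations, double dt, double beta,
                      double cap) {
  const int N = x.size() / 3;
  const int M = tets.nrow();
  const int Fn = faces.nrow();
  const int Q = quads.nrow();
  const int n_steps = facA.size();

  std::vector<double> X(x.begin(), x.end());
  std::vector<double> W(invmass.begin(), invmass.end());
  std::vector<double> FM(freemask.begin(), freemask.end());
  std::vector<double> DM(Dm.begin(), Dm.end());
  std::vector<double> DMI(9 * (size_t)M);
  std::vector<int> TV(4 * (size_t)M);
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < 4; ++k) TV[4 * m + k] = tets(m, k);
  std::vector<int> FV(3 * (size_t)Fn);
  for (int f = 0; f < Fn; ++f)
    for (int k = 0; k < 3; ++k) FV[3 * f + k] = faces(f, k);
  std::vector<int> QV(4 * (size_t)Q);
  for (int q = 0; q < Q; ++q)
    for (int k = 0; k < 4; ++k) QV[4 * q + k] = quads(q, k);
  std::vector<double> RA(restA.begin(), restA.end());
  std::vector<double> RL(restL.begin(), restL.end());

  for (int m = 0; m < M; ++m) {
    if (!inv3(&DM[9 * m], &DMI[9 * m]))
      stop("singular rest matrix in tetrahedron %d", m + 1);
  }

  std::vector<double> lamH(M), lamD(M), lamA(Fn), lamS(Q);
  NumericVector resH(n_steps), resD(n_steps), resA(n_steps), resS(n_steps);
  IntegerVector inverted(n_steps);
  const double dt_sub = dt / substeps;
  const double idt2 = 1.0 / (dt_sub * dt_sub);
  const double kappa = (beta <= 0.0) ? 0.0 : (1.0 - std::exp(-beta * dt));
  bool bad = false;

  for (int s = 0; s < n_steps && !bad; ++s) {
    for (int f = 0; f < Fn; ++f) RA[f] *= facA[s];
    for (int q = 0; q < Q; ++q) RL[q] *= facL[s];

    double rH = 0, rD = 0, rA = 0, rS = 0;
    int ninv = 0;
    for (int sub = 0; sub < substeps; ++sub) {
      std::fill(lamH.begin(), lamH.end(), 0.0);
      std::fill(lamD.begin(), lamD.end(), 0.0);
      std::fill(lamA.begin(), lamA.end(), 0.0);
      std::fill(lamS.begin(), lamS.end(), 0.0);
      bool last = (sub == substeps - 1);
      for (int it = 0; it < iterations; ++it) {
        bool record = last && (it == iterations - 1);
        if (record) { rH = rD = rA = rS = 0; ninv = 0; }
        for (int m = 0; m < M; ++m) {
          double detDs = 0.0, cH = 0.0, dd = 0.0;
          proj_tet_pair(&X[0], &W[0], &FM[0], &TV[4 * m], &DMI[9 * m],
                        restvol[m], gammaH[m], alphaH[m] * idt2,
                        alphaD[m] * idt2, &lamH[m], &lamD[m], cap,
                        &cH, &dd, &detDs);
          if (record) {
            if (cH > rH) rH = cH;
            if (dd > rD) rD = dd;
            if (detDs <= 0.0) ++ninv;
          }
        }
        for (int f = 0; f < Fn; ++f) {
          double c = proj_area(&X[0], &W[0], &FM[0], &FV[3 * f], RA[f],
                               alphaA[f] * idt2, &lamA[f], cap, true);
          if (record && c > rA) rA = c;
        }
        for (int q = 0; q < Q; ++q) {
          double c = proj_smooth(&X[0], &W[0], &FM[0], &QV[4 * q], RL[q],
                                 alphaS[q] * idt2, &lamS[q], cap, true);
          if (record && c > rS) rS = c;
        }
      }
    }

    if (kappa > 0.0) {
      for (int m = 0; m < M; ++m) {
        double Ds[9];
        edge_matrix(&X[0], &TV[4 * m], Ds);
        double tmp[9];
        for (int k = 0; k < 9; ++k)
          tmp[k] = (1.0 - kappa) * DM[9 * m + k] + kappa * Ds[k];
        double di[9];
        if (det3(tmp) > 1e-14 && inv3(tmp, di)) {
          for (int k = 0; k < 9; ++k) { DM[9 * m + k] = tmp[k]; DMI[9 * m + k] = di[k]; }
        }  // else keep the previous rest pose (degenerate blend)
      }
    }

    resH[s] = rH; resD[s] = rD; resA[s] = rA; resS[s] = rS;
    inverted[s] = ninv;
    for (int i = 0; i < 3 * N; ++i)
      if (!std::isfinite(X[i])) { bad = true; break; }
  }

  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["Dm"] = NumericVector(DM.begin(), DM.end()),
                      _["restA"] = NumericVector(RA.begin(), RA.end()),
                      _["restL"] = NumericVector(RL.begin(), RL.end()),
                      _["res_hydro"] = resH, _["res_dev"] = resD,
                      _["res_area"] = resA, _["res_smooth"] = resS,
                      _["inverted"] = inverted, _["nan_abort"] = bad);
}

// ---- single-constraint entry points (unit-test surface) -------------------

// [[Rcpp::export]]
List cpp_project_tet(NumericVector x, NumericVector invmass,
                     NumericVector freemask, IntegerVector verts, double V0,
                     double gammaH, NumericVector Dm, double alphaH,
                     double alphaD, double dt_sub, double lamH, double lamD,
                     double cap) {
  std::vector<double> X(x.begin(), x.end());
  double DMI[9];
  if (!inv3(&Dm[0], DMI)) stop("singular rest matrix");
  int v[4] = { verts[0], verts[1], verts[2], verts[3] };
  double idt2 = 1.0 / (dt_sub * dt_sub);
  double cH = proj_tet_H(&X[0], &invmass[0], &freemask[0], v, V0, gammaH,
                         alphaH * idt2, &lamH, cap, nullptr);
  double cD = proj_tet_D(&X[0], &invmass[0], &freemask[0], v, DMI,
                         alphaD * idt2, &lamD, cap);
  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["lamH"] = lamH, _["lamD"] = lamD,
                      _["absC_H"] = cH, _["C_D"] = cD);
}

// [[Rcpp::export]]
List cpp_project_area(NumericVector x, NumericVector invmass,
                      NumericVector freemask, IntegerVector verts, double R,
                      double alpha, double dt_sub, double lambda, double cap) {
  std::vector<double> X(x.begin(), x.end());
  int v[3] = { verts[0], verts[1], verts[2] };
  double c = proj_area(&X[0], &invmass[0], &freemask[0], v, R,
                       alpha / (dt_sub * dt_sub), &lambda, cap);
  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["lambda"] = lambda, _["absC"] = c);
}

// [[Rcpp::export]]
List cpp_project_smooth(NumericVector x, NumericVector invmass,
                        NumericVector freemask, IntegerVector verts, double L,
                        double alpha, double dt_sub, double lambda, double cap) {
  std::vector<double> X(x.begin(), x.end());
  int v[4] = { verts[0], verts[1], verts[2], verts[3] };
  double c = proj_smooth(&X[0], &invmass[0], &freemask[0], v, L,
                         alpha / (dt_sub * dt_sub), &lambda, cap);
  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["lambda"] = lambda, _["absC"] = c);
}
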