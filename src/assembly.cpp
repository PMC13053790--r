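// Total-Lagrangian assembly kernels for trilinear hexahedra.
//
// Passive material: transversely isotropic exponential strain energy
//   W = (C/2)(e^Q - 1),  Q = b1 E11^2 + b2(E22^2+E33^2+E23^2+E32^2)
//                            + b3(E12^2+E21^2+E13^2+E31^2)
// evaluated in the fiber frame (axis 1 = fiber). Near-incompressibility is
// enforced by a volumetric penalty U = (kappa/2)(J-1)^2 integrated at the
// element centre only (selective reduced integration, avoids locking);
// the deviatoric + active terms use full 2x2x2 Gauss quadrature.
//
// Active stress: second Piola-Kirchhoff diag(T0, 0.4 T0, 0.4 T0) in the
// fiber frame with T0 the length-dependent tension of the sarcomere model.

#include <RcppArmadillo.h>
using namespace arma;

static const double GP = 0.5773502691896258; // 1/sqrt(3)

// dN/dxi for trilinear hex at (xi, eta, zeta); rows = node, cols = xi dir
static void shape_grad(double xi, double eta, double zeta, mat &dN) {
  // node order: (-,-,-) (+,-,-) (+,+,-) (-,+,-) (-,-,+) (+,-,+) (+,+,+) (-,+,+)
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * sx[a] * (1 + sy[a] * eta) * (1 + sz[a] * zeta);
    dN(a, 1) = 0.125 * sy[a] * (1 + sx[a] * xi) * (1 + sz[a] * zeta);
    dN(a, 2) = 0.125 * sz[a] * (1 + sx[a] * xi) * (1 + sy[a] * eta);
  }
}

struct ActivePars {
  double tmax, l0, lR, B, ca0, ca0max, ct;
  bool on;
};

// length-dependent tension and its derivative w.r.t. fiber Green strain
static void t0_and_deriv(double e11, const ActivePars &ap,
                         double &t0, double &dt0) {
  t0 = 0.0; dt0 = 0.0;
  double arg = 2.0 * e11 + 1.0;
  if (arg <= 0) return;
  double l = ap.lR * std::sqrt(arg);
  if (l <= ap.l0) return;
  double g = std::expm1(ap.B * (l - ap.l0));
  double ca2 = ap.ca0 * ap.ca0, cam2 = ap.ca0max * ap.ca0max;
  double den = ca2 * g + cam2;
  t0 = ap.tmax * ca2 * g / den;
  double dgdl = (g + 1.0) * ap.B;
  double dlde = ap.lR * ap.lR / l; // dl/de11
  double dt0dg = ap.tmax * ca2 * cam2 / (den * den);
  dt0 = dt0dg * dgdl * dlde;
}

// B-matrix (6x24) for variation of fiber-frame Green strain, built from the
// fiber-rotated deformation gradient Ft = F R and gradients Gt = G R.
static void fill_B(const mat &Ft, const mat &Gt, mat &B) {
  for (int a = 0; a < 8; ++a) {
    for (int j = 0; j < 3; ++j) {
      int c = 3 * a + j;
      B(0, c) = Ft(j, 0) * Gt(a, 0);
      B(1, c) = Ft(j, 1) * Gt(a, 1);
      B(2, c) = Ft(j, 2) * Gt(a, 2);
      B(3, c) = Ft(j, 1) * Gt(a, 2) + Ft(j, 2) * Gt(a, 1);
      B(4, c) = Ft(j, 0) * Gt(a, 2) + Ft(j, 2) * Gt(a, 0);
      B(5, c) = Ft(j, 0) * Gt(a, 1) + Ft(j, 1) * Gt(a, 0);
    }
  }
}

// [[Rcpp::export(name = ".cpp_assemble")]]
Rcpp::List cpp_assemble(const arma::mat &nodes,      // N x 3 (m)
                        const arma::imat &conn,      // M x 8, 1-based
                        const arma::vec &disp,       // 3N (m), dof = 3(n-1)+i
                        const arma::mat &rot,        // M x 9, column-major R
                        const arma::mat &matpar,     // M x 4: C, b1, b2, b3
                        const arma::vec &active_flag,// M
                        double kappa,
                        Rcpp::List active,           // tmax,l0,lR,big_b,ca0,ca0max
                        double ct,
                        bool want_K) {
  const int M = conn.n_rows;
  const int N = nodes.n_rows;
  vec fint(3 * N, fill::zeros);

  ActivePars ap;
  ap.tmax = Rcpp::as<double>(active["t_max"]);
  ap.l0 = Rcpp::as<double>(active["l0"]);
  ap.lR = Rcpp::as<double>(active["lR"]);
  ap.B = Rcpp::as<double>(active["big_b"]);
  ap.ca0 = Rcpp::as<double>(active["ca0"]);
  ap.ca0max = Rcpp::as<double>(active["ca0_max"]);
  ap.ct = ct;

  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_K) { Ti.reserve(M * 576); Tj.reserve(M * 576); Tx.reserve(M * 576); }

  mat dN(8, 3), X(8, 3), u(8, 3), G(8, 3), Gt(8, 3);
  mat F(3, 3), Ft(3, 3), Ef(3, 3), B(6, 24);
  mat Ke(24, 24), D(6, 6);
  vec fe(24);
  const mat I3 = eye(3, 3);
  bool bad = false;

  const int map1[6] = {0, 1, 2, 1, 0, 0}; // Voigt index pairs
  const int map2[6] = {0, 1, 2, 2, 2, 1};

  for (int e = 0; e < M; ++e) {
    uvec en(8);
    for (int a = 0; a < 8; ++a) en(a) = conn(e, a) - 1;
    for (int a = 0; a < 8; ++a) {
      X.row(a) = nodes.row(en(a));
      for (int i = 0; i < 3; ++i) u(a, i) = disp(3 * en(a) + i);
    }
    mat R(3, 3);
    for (int c = 0, k = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r, ++k) R(r, c) = rot(e, k);

    const double Cm = matpar(e, 0);
    vec qw = {matpar(e, 1), matpar(e, 2), matpar(e, 2),
              matpar(e, 2) / 2.0, matpar(e, 3) / 2.0, matpar(e, 3) / 2.0};
    const bool act_on = active_flag(e) > 0.5 && ct > 0;

    fe.zeros();
    if (want_K) Ke.zeros();

    // ---- deviatoric + active: 2x2x2 Gauss ----
    for (int g1 = -1; g1 <= 1; g1 += 2)
      for (int g2 = -1; g2 <= 1; g2 += 2)
        for (int g3 = -1; g3 <= 1; g3 += 2) {
          shape_grad(g1 * GP, g2 * GP, g3 * GP, dN);
          mat J0 = dN.t() * X; // 3x3, d x / d xi
          double dJ0 = det(J0);
          if (dJ0 <= 0) { bad = true; }
          G = dN * inv(J0.t()); // G(a,J) = dN_a/dX_J
          F = I3 + u.t() * G;
          Ft = F * R;
          Gt = G * R;
          Ef = 0.5 * (Ft.t() * Ft - I3);
          vec v = {Ef(0, 0), Ef(1, 1), Ef(2, 2),
                   2 * Ef(1, 2), 2 * Ef(0, 2), 2 * Ef(0, 1)};
          double Q = dot(qw, v % v);
          double ceq = Cm * std::exp(Q);
          vec Sv = ceq * (qw % v);
          double t0 = 0, dt0 = 0;
          if (act_on) {
            t0_and_deriv(Ef(0, 0), ap, t0, dt0);
            Sv(0) += ap.ct * t0;
            Sv(1) += 0.4 * ap.ct * t0;
            Sv(2) += 0.4 * ap.ct * t0;
          }
          fill_B(Ft, Gt, B);
          double w = dJ0; // unit gauss weights
          fe += w * (B.t() * Sv);
          if (want_K) {
            vec qv = qw % v;
            D = ceq * (diagmat(qw) + 2.0 * (qv * qv.t()));
            if (act_on) {
              D(0, 0) += ap.ct * dt0;
              D(1, 0) += 0.4 * ap.ct * dt0;
              D(2, 0) += 0.4 * ap.ct * dt0;
            }
            Ke += w * (B.t() * D * B);
            // geometric stiffness with fiber-frame S
            mat S3(3, 3);
            S3(0, 0) = Sv(0); S3(1, 1) = Sv(1); S3(2, 2) = Sv(2);
            S3(1, 2) = S3(2, 1) = Sv(3);
            S3(0, 2) = S3(2, 0) = Sv(4);
            S3(0, 1) = S3(1, 0) = Sv(5);
            mat H = Gt * S3 * Gt.t(); // 8x8
            for (int a = 0; a < 8; ++a)
              for (int b = 0; b < 8; ++b) {
                double h = w * H(a, b);
                Ke(3 * a, 3 * b) += h;
                Ke(3 * a + 1, 3 * b + 1) += h;
                Ke(3 * a + 2, 3 * b + 2) += h;
              }
          }
        }

    // ---- volumetric penalty: single centre point, weight 8 ----
    if (kappa > 0) {
      shape_grad(0, 0, 0, dN);
      mat J0 = dN.t() * X;
      double dJ0 = det(J0);
      G = dN * inv(J0.t());
      F = I3 + u.t() * G;
      double Jd = det(F);
      if (Jd <= 0) bad = true;
      mat Cfull = F.t() * F;
      mat Cinv = inv_sympd((Cfull + Cfull.t()) / 2);
      mat Svol = kappa * (Jd - 1.0) * Jd * Cinv;
      vec Sv = {Svol(0, 0), Svol(1, 1), Svol(2, 2),
                Svol(1, 2), Svol(0, 2), Svol(0, 1)};
      fill_B(F, G, B); // global frame (R = I)
      double w = 8.0 * dJ0;
      fe += w * (B.t() * Sv);
      if (want_K) {
        double c1 = kappa * (2.0 * Jd - 1.0) * Jd;
        double c2 = kappa * (Jd - 1.0) * Jd;
        for (int al = 0; al < 6; ++al) {
          int Jb = map1[al], K = map2[al];
          for (int be = 0; be < 6; ++be) {
            int L = map1[be], Mi = map2[be];
            double d = c1 * Cinv(Jb, K) * Cinv(L, Mi)
              - c2 * (Cinv(Jb, L) * Cinv(K, Mi) + Cinv(Jb, Mi) * Cinv(K, L));
            D(al, be) = d;
          }
        }
        Ke += w * (B.t() * D * B);
        mat H = G * Svol * G.t();
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double h = w * H(a, b);
            Ke(3 * a, 3 * b) += h;
            Ke(3 * a + 1, 3 * b + 1) += h;
            Ke(3 * a + 2, 3 * b + 2) += h;
          }
      }
    }

    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        fint(3 * en(a) + i) += fe(3 * a + i);

    if (want_K) {
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * en(a) + i;
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              Ti.push_back(gi + 1);
              Tj.push_back(3 * en(b) + j + 1);
              Tx.push_back(Ke(3 * a + i, 3 * b + j));
            }
        }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("f") = fint,
    Rcpp::Named("bad") = bad);
  if (want_K) {
    out["ki"] = Rcpp::IntegerVector(Ti.begin(), Ti.end());
    out["kj"] = Rcpp::IntegerVector(Tj.begin(), Tj.end());
    out["kx"] = Rcpp::NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// Per-element centre strains: fiber-frame Green strain (Voigt), global-frame
// Green strain (Voigt), deformation Jacobian, and reference volume.
// [[Rcpp::export(name = ".cpp_element_strains")]]
Rcpp::NumericMatrix cpp_element_strains(const arma::mat &nodes,
                                        const arma::imat &conn,
                                        const arma::vec &disp,
                                        const arma::mat &rot) {
  const int M = conn.n_rows;
  Rcpp::NumericMatrix out(M, 14);
  mat dN(8, 3), X(8, 3), u(8, 3);
  const mat I3 = eye(3, 3);
  shape_grad(0, 0, 0, dN);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = conn(e, a) - 1;
      X.row(a) = nodes.row(n);
      for (int i = 0; i < 3; ++i) u(a, i) = disp(3 * n + i);
    }
    mat R(3, 3);
    for (int c = 0, k = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r, ++k) R(r, c) = rot(e, k);
    mat J0 = dN.t() * X;
    mat G = dN * inv(J0.t());
    mat F = I3 + u.t() * G;
    mat Eg = 0.5 * (F.t() * F - I3);
    mat Ef = R.t() * Eg * R;
    double vals[14] = {Ef(0, 0), Ef(1, 1), Ef(2, 2), Ef(1, 2), Ef(0, 2), Ef(0, 1),
                       Eg(0, 0), Eg(1, 1), Eg(2, 2), Eg(1, 2), Eg(0, 2), Eg(0, 1),
                       det(F), 8.0 * det(J0)};
    for (int k = 0; k < 14; ++k) out(e, k) = vals[k];
  }
  return out;
}

// Positive-Jacobian check: min det(dx/dxi) over the 2x2x2 Gauss points.
// [[Rcpp::export(name = ".cpp_min_jacobian")]]
Rcpp::NumericVector cpp_min_jacobian(const arma::mat &nodes,
                                     const arma::imat &conn) {
  const int M = conn.n_rows;
  Rcpp::NumericVector out(M);
  mat dN(8, 3), X(8, 3);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) X.row(a) = nodes.row(conn(e, a) - 1);
    double mn = datum::inf;
    for (int g1 = -1; g1 <= 1; g1 += 2)
      for (int g2 = -1; g2 <= 1; g2 += 2)
        for (int g3 = -1; g3 <= 1; g3 += 2) {
          shape_grad(g1 * GP, g2 * GP, g3 * GP, dN);
          mn = std::min(mn, det(dN.t() * X));
        }
    out(e) = mn;
  }
  return out;
}

// Follower endocardial pressure: nodal forces and (nonsymmetric) load
// stiffness of p * n dA integrated over deformed bilinear facets with
// 2x2 Gauss points. Facet orientation: cross(t_xi, t_eta) points from the
// cavity into the wall, which is the direction of the applied traction.
// [[Rcpp::export(name = ".cpp_pressure")]]
Rcpp::List cpp_pressure(const arma::mat &nodes,   // N x 3 (m)
                        const arma::imat &facets, // F x 4, 1-based
                        const arma::vec &disp,    // 3N (m)
                        double p,
                        bool want_K) {
  const int N = nodes.n_rows;
  const int Fn = facets.n_rows;
  vec fext(3 * N, fill::zeros);
  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_K) { Ti.reserve(Fn * 144); Tj.reserve(Fn * 144); Tx.reserve(Fn * 144); }
  const double g = 0.5773502691896258;
  const double gx[4] = {-g, g, g, -g}, ge[4] = {-g, -g, g, g};
  mat x(4, 3);
  for (int fi = 0; fi < Fn; ++fi) {
    uvec ids(4);
    for (int a = 0; a < 4; ++a) {
      ids(a) = facets(fi, a) - 1;
      for (int i = 0; i < 3; ++i)
        x(a, i) = nodes(ids(a), i) + disp(3 * ids(a) + i);
    }
    for (int q = 0; q < 4; ++q) {
      double xi = gx[q], eta = ge[q];
      vec Nf = {0.25 * (1 - xi) * (1 - eta), 0.25 * (1 + xi) * (1 - eta),
                0.25 * (1 + xi) * (1 + eta), 0.25 * (1 - xi) * (1 + eta)};
      vec dXi = {-0.25 * (1 - eta), 0.25 * (1 - eta),
                 0.25 * (1 + eta), -0.25 * (1 + eta)};
      vec dEt = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                 0.25 * (1 + xi), 0.25 * (1 - xi)};
      rowvec t1 = dXi.t() * x, t2 = dEt.t() * x;
      vec nv = {t1(1) * t2(2) - t1(2) * t2(1),
                t1(2) * t2(0) - t1(0) * t2(2),
                t1(0) * t2(1) - t1(1) * t2(0)};
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          fext(3 * ids(a) + i) += p * Nf(a) * nv(i);
      if (want_K) {
        // d nv / d u_{b,j} = dXi_b (e_j x t2) + dEt_b (t1 x e_j)
        for (int b = 0; b < 4; ++b) {
          mat dn(3, 3, fill::zeros);
          for (int j = 0; j < 3; ++j) {
            vec ej(3, fill::zeros); ej(j) = 1.0;
            vec c1 = {ej(1) * t2(2) - ej(2) * t2(1),
                      ej(2) * t2(0) - ej(0) * t2(2),
                      ej(0) * t2(1) - ej(1) * t2(0)};
            vec c2 = {t1(1) * ej(2) - t1(2) * ej(1),
                      t1(2) * ej(0) - t1(0) * ej(2),
                      t1(0) * ej(1) - t1(1) * ej(0)};
            for (int i = 0; i < 3; ++i)
              dn(i, j) = dXi(b) * c1(i) + dEt(b) * c2(i);
          }
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) {
                Ti.push_back(3 * ids(a) + i + 1);
                Tj.push_back(3 * ids(b) + j + 1);
                Tx.push_back(p * Nf(a) * dn(i, j));
              }
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("f") = fext);
  if (want_K) {
    out["ki"] = Rcpp::IntegerVector(Ti.begin(), Ti.end());
    out["kj"] = Rcpp::IntegerVector(Tj.begin(), Tj.end());
    out["kx"] = Rcpp::NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

#include <R_ext/Lapack.h>

// Solve a sparse system via LAPACK banded LU (dgbsv). Triplets must already
// be mapped to contiguous 1-based indices; kl/ku are the lower/upper
// bandwidths of the pattern. Returns the solution, or a vector of NaN if
// the factorization fails.
// [[Rcpp::export(name = ".cpp_band_solve")]]
Rcpp::NumericVector cpp_band_solve(const Rcpp::IntegerVector &ti,
                                   const Rcpp::IntegerVector &tj,
                                   const Rcpp::NumericVector &tx,
                                   const Rcpp::NumericVector &b,
                                   int kl, int ku) {
  const int n = b.size();
  const int ldab = 2 * kl + ku + 1;
  std::vector<double> AB((size_t)ldab * n, 0.0);
  const int nt = ti.size();
  for (int t = 0; t < nt; ++t) {
    int i = ti[t] - 1, j = tj[t] - 1;
    AB[(size_t)j * ldab + (kl + ku + i - j)] += tx[t];
  }
  std::vector<int> ipiv(n);
  Rcpp::NumericVector x = Rcpp::clone(b);
  int nrhs = 1, info = 0;
  F77_CALL(dgbsv)(&n, &kl, &ku, &nrhs, AB.data(), &ldab, ipiv.data(),
                  REAL(x), &n, &info);
  if (info != 0) std::fill(x.begin(), x.end(), NA_REAL);
  return x;
}
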